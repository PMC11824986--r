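ARCHIVE_VERSION <- "costelm-archive-1"

# Atomic write contract: serialize to a temp file in the same directory, then
# rename over the destination.
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

mat_to_list <- function(m) {
  list(data = as.vector(m), nrow = nrow(m), ncol = ncol(m))
}

list_to_mat <- function(l) matrix(l$data, l$nrow, l$ncol)

serialize_layer <- function(layer) {
  if (is.null(layer)) return(NULL)
  list(weights = mat_to_list(layer$weights), biases = layer$biases,
       activation = layer$activation, distribution = layer$distribution,
       seed = layer$seed)
}

deserialize_layer <- function(l) {
  if (is.null(l)) return(NULL)
  structure(
    list(weights = list_to_mat(l$weights), biases = as.numeric(l$biases),
         activation = l$activation, distribution = l$distribution,
         seed = as.integer(l$seed)),
    class = "random_layer"
  )
}

serialize_encoder <- function(enc) {
  list(
    variant = enc$variant,
    random_layer = serialize_layer(enc$random_layer),
    kernel = if (is.null(enc$kernel)) NULL else
      list(family = enc$kernel$family, sigma = enc$kernel$sigma),
    references = if (is.null(enc$references)) NULL else
      list(points = mat_to_list(enc$references$points),
           source_indices = enc$references$source_indices,
           seed = enc$references$seed),
    gamma = mat_to_list(enc$gamma),
    regularization = enc$regularization,
    input_dim = enc$input_dim
  )
}

deserialize_encoder <- function(l) {
  new_encoder_model(
    l$variant,
    gamma = list_to_mat(l$gamma),
    C = l$regularization,
    input_dim = l$input_dim,
    random_layer = deserialize_layer(l$random_layer),
    kernel = if (is.null(l$kernel)) NULL else
      kernel_spec(l$kernel$family, l$kernel$sigma),
    references = if (is.null(l$references)) NULL else
      structure(
        list(points = list_to_mat(l$references$points),
             source_indices = as.integer(l$references$source_indices),
             seed = as.integer(l$references$seed)),
        class = "reference_set"
      )
  )
}

serialize_classifier <- function(clf) {
  list(hidden_layer = serialize_layer(clf$hidden_layer),
       beta = list(coefficients = mat_to_list(clf$beta$coefficients),
                   regularization = clf$beta$regularization,
                   solve_form = clf$beta$solve_form),
       classes = clf$classes, target_coding = clf$target_coding,
       regularization = clf$regularization, seed = clf$seed)
}

deserialize_classifier <- function(l) {
  structure(
    list(hidden_layer = deserialize_layer(l$hidden_layer),
         beta = structure(
           list(coefficients = list_to_mat(l$beta$coefficients),
                regularization = l$beta$regularization,
                solve_form = l$beta$solve_form),
           class = "ridge_solution"
         ),
         classes = as.character(l$classes), target_coding = l$target_coding,
         regularization = l$regularization, seed = as.integer(l$seed)),
    class = "elm_classifier"
  )
}

#' Save a multi-kernel ELM to a JSON archive
#'
#' Writes every weight matrix, reference point, kernel parameter and seed at
#' full double precision so a reloaded model reproduces predictions
#' bit-identically. The write is atomic (temp file + rename).
#'
#' @param model A fitted `mk_elm`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "mk_elm")) stop("`model` must be an mk_elm", call. = FALSE)
  payload <- list(
    version = ARCHIVE_VERSION,
    architecture = model$architecture,
    encoders = lapply(model$encoders, serialize_encoder),
    classifier = serialize_classifier(model$classifier),
    sizing = model$sizing, L = model$L, C = model$C, seed = model$seed,
    input_dim = model$input_dim, label = model$label
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
  })
}

#' Load a multi-kernel ELM from a JSON archive
#'
#' @param path Path written by [save_model()]. Unreadable or
#'   wrong-version archives raise a clean error.
#' @return The restored `mk_elm`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    error = function(e) stop("not a readable model archive: ", path,
                             call. = FALSE)
  )
  if (!identical(payload$version, ARCHIVE_VERSION)) {
    stop("archive version mismatch (found ",
         payload$version %||% "<none>", ", expected ", ARCHIVE_VERSION, ")",
         call. = FALSE)
  }
  structure(
    list(
      architecture = payload$architecture,
      encoders = lapply(payload$encoders, deserialize_encoder),
      classifier = deserialize_classifier(payload$classifier),
      sizing = payload$sizing, L = payload$L, C = payload$C,
      seed = as.integer(payload$seed), input_dim = as.integer(payload$input_dim),
      label = payload$label %||% NA_character_
    ),
    class = c(paste0(payload$architecture, "_elm"), "mk_elm")
  )
}

#' Write / read a cost matrix as delimited text
#'
#' Plain CSV with a header row of class labels and the class labels as the
#' first column; readable by any spreadsheet. Writing is atomic.
#'
#' @param cost A [cost_matrix()].
#' @param path File path.
#' @return `write_cost_matrix()` returns `path` invisibly;
#'   `read_cost_matrix()` returns a `cost_matrix`.
#' @export
write_cost_matrix <- function(cost, path) {
  df <- data.frame(class = cost$class_order, cost$costs, check.names = FALSE)
  atomic_write(path, function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE)
  })
}

#' @rdname write_cost_matrix
#' @export
read_cost_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labs <- as.character(df[[1]])
  costs <- as.matrix(df[, -1, drop = FALSE])
  cost_matrix(costs, labs)
}

#' Write a dataset as delimited text
#'
#' Comma-separated with a header row; the label column keeps its name.
#' Writing is atomic.
#'
#' @param data Data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  atomic_write(path, function(tmp) {
    utils::write.csv(as.data.frame(data), tmp, row.names = FALSE)
  })
}

#' Read a delimited dataset
#'
#' @param path CSV file with a header row.
#' @param label Label column name; when present the column becomes a factor.
#' @return A tibble.
#' @export
read_dataset <- function(path, label = "label") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (label %in% names(df)) df[[label]] <- factor(df[[label]])
  tibble::as_tibble(df)
}
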