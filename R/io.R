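# doubles are printed with %.17g so that write -> read is bit-faithful at
# full double precision
fmt_dbl <- function(x) sprintf("%.17g", x)

#' Read and write labeled datasets as delimited text
#'
#' The feature file is a CSV with a header of feature ids and a leading
#' `sample_id` column; the labels file is a two-column CSV
#' (`sample_id,label` with labels in \{-1, 1\}). Numeric values are written
#' with 17 significant digits, so a write/read round trip reproduces the
#' doubles bit-exactly.
#'
#' @param data a [labeled_dataset()].
#' @param features_path,labels_path file paths.
#' @return `write_dataset` returns the paths invisibly; `read_dataset`
#'   returns a [labeled_dataset()].
#' @export
write_dataset <- function(data, features_path, labels_path) {
  stopifnot(inherits(data, "labeled_dataset"))
  fm <- matrix(fmt_dbl(data$features), nrow = nrow(data$features))
  lines <- c(paste(c("sample_id", data$feature_ids), collapse = ","),
             paste(data$sample_ids, apply(fm, 1, paste, collapse = ","),
                   sep = ","))
  writeLines(lines, features_path)
  write.csv(data.frame(sample_id = data$sample_ids, label = data$labels),
            labels_path, row.names = FALSE, quote = FALSE)
  invisible(c(features = features_path, labels = labels_path))
}

#' @rdname write_dataset
#' @export
read_dataset <- function(features_path, labels_path) {
  fm <- read.csv(features_path, check.names = FALSE)
  if (!"sample_id" %in% colnames(fm)) {
    stop("feature file must carry a 'sample_id' column: ", features_path)
  }
  lab <- read.csv(labels_path)
  if (!all(c("sample_id", "label") %in% colnames(lab))) {
    stop("labels file must have columns sample_id,label: ", labels_path)
  }
  ord <- match(fm$sample_id, lab$sample_id)
  if (anyNA(ord)) stop("sample ids of features and labels do not match")
  X <- as.matrix(fm[, setdiff(colnames(fm), "sample_id"), drop = FALSE])
  labeled_dataset(X, lab$label[ord], sample_ids = fm$sample_id,
                  feature_ids = setdiff(colnames(fm), "sample_id"))
}

model_record <- function(model) {
  list(
    type = "wsvm_model",
    support_vectors = unclass(model$support_vectors),
    support_labels = model$support_labels,
    support_weights = model$support_weights,
    dual_coefs = model$dual_coefs,
    coefs = model$coefs,
    bias = model$bias,
    C = model$C,
    kernel = unclass(model$kernel),
    n_features = model$n_features,
    sv_index = model$sv_index,
    alpha_full = model$alpha_full,
    weights_full = model$weights_full,
    objective = model$objective,
    iterations = model$iterations,
    converged = model$converged,
    kkt_violation = model$kkt_violation)
}

model_from_record <- function(rec) {
  n_sv <- length(rec$support_labels)
  sv <- matrix(as.numeric(unlist(rec$support_vectors)), nrow = n_sv,
               ncol = as.integer(rec$n_features), byrow = TRUE)
  structure(
    list(support_vectors = sv,
         support_labels = as.numeric(unlist(rec$support_labels)),
         support_weights = as.numeric(unlist(rec$support_weights)),
         dual_coefs = as.numeric(unlist(rec$dual_coefs)),
         coefs = as.numeric(unlist(rec$coefs)),
         bias = as.numeric(rec$bias),
         C = as.numeric(rec$C),
         kernel = structure(list(name = rec$kernel$name,
                                 sigma = as.numeric(rec$kernel$sigma)),
                            class = "kernel_spec"),
         n_features = as.integer(rec$n_features),
         sv_index = as.integer(unlist(rec$sv_index)),
         alpha_full = as.numeric(unlist(rec$alpha_full)),
         weights_full = as.numeric(unlist(rec$weights_full)),
         objective = as.numeric(rec$objective),
         iterations = as.integer(rec$iterations),
         converged = as.logical(rec$converged),
         kkt_violation = as.numeric(rec$kkt_violation)),
    class = "wsvm_model")
}

#' Serialize fitted models as JSON
#'
#' Flat JSON records holding every field of the fitted object at 17
#' significant digits, so that save/load round trips are faithful at full
#' double precision. Support-vector matrices are stored row-major.
#'
#' @param model a `wsvm_model`.
#' @param path output file.
#' @return the path, invisibly (`save_*`); the reconstructed object
#'   (`load_*`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wsvm_model"))
  writeLines(jsonlite::toJSON(model_record(model), digits = I(17),
                              auto_unbox = TRUE, matrix = "rowmajor"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(rec$type, "wsvm_model")) {
    stop("not a serialized wsvm_model: ", path)
  }
  model_from_record(rec)
}

#' @rdname save_model
#' @param ensemble a `boosted_ensemble`.
#' @export
save_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "boosted_ensemble"))
  rec <- list(
    type = "boosted_ensemble",
    vote_weights = ensemble$vote_weights,
    train_errors = ensemble$train_errors,
    final_weights = ensemble$final_weights,
    C = ensemble$C,
    kernel = unclass(ensemble$kernel),
    config = unclass(ensemble$config),
    units_features = unclass(ensemble$units$features),
    units_labels = ensemble$units$labels,
    shared_units = isTRUE(ensemble$shared_units),
    weak_models = lapply(ensemble$weak_models, model_record))
  writeLines(jsonlite::toJSON(rec, digits = I(17), auto_unbox = TRUE,
                              matrix = "rowmajor"), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_ensemble <- function(path) {
  rec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(rec$type, "boosted_ensemble")) {
    stop("not a serialized boosted_ensemble: ", path)
  }
  labels <- as.numeric(unlist(rec$units_labels))
  units <- labeled_dataset(
    matrix(as.numeric(unlist(rec$units_features)), nrow = length(labels),
           byrow = TRUE),
    labels)
  structure(
    list(weak_models = lapply(rec$weak_models, model_from_record),
         vote_weights = as.numeric(unlist(rec$vote_weights)),
         train_errors = as.numeric(unlist(rec$train_errors)),
         units = units,
         final_weights = as.numeric(unlist(rec$final_weights)),
         C = as.numeric(rec$C),
         kernel = structure(list(name = rec$kernel$name,
                                 sigma = as.numeric(rec$kernel$sigma)),
                            class = "kernel_spec"),
         config = boost_config(rec$config$M, rec$config$err_floor,
                               rec$config$err_ceiling,
                               rec$config$recluster_each_round),
         shared_units = isTRUE(rec$shared_units)),
    class = "boosted_ensemble")
}
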