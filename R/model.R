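# Epsilon-SVR efficacy model: training, prediction, cross-validation, metrics
#
# The regressor is an epsilon-SVR with RBF kernel (e1071/libsvm). The
# hyperparameter triple (g, c, j) maps g -> gamma and c -> cost; j is an
# SVM-light regression parameter with no exact libsvm analog, so it is kept
# in the bundle for provenance and mapped to the epsilon tube width as
# j / 100 (documented caveat; see the methods vignette).

MODEL_FORMAT_VERSION <- 1L

default_hyperparams <- function() list(g = 0.001, c = 2, j = 1)

check_hyperparams <- function(h) {
  if (!is.list(h) || !all(c("g", "c", "j") %in% names(h))) {
    stop("hyperparams must be a list with elements g, c and j", call. = FALSE)
  }
  for (nm in c("g", "c", "j")) {
    v <- h[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("hyperparameter '", nm, "' must be a single positive number",
           call. = FALSE)
    }
  }
  h[c("g", "c", "j")]
}

#' Train the SVR efficacy model
#'
#' Fits the min-max scaler on the training feature matrix, then an
#' epsilon-SVR with RBF kernel on the scaled features. Training is
#' deterministic given the same records and hyperparameters.
#'
#' @param records siRNA records: a data frame with columns \code{antisense}
#'   and \code{efficacy} (plus optional \code{id}, \code{accessibility}),
#'   e.g. from \code{\link{read_sirna_table}} or
#'   \code{\link{generate_synthetic}}.
#' @param spec an \code{\link{encoding_spec}}.
#' @param hyperparams list with \code{g} (RBF gamma), \code{c} (cost) and
#'   \code{j} (mapped to epsilon = j/100). Default \code{g = 0.001, c = 2,
#'   j = 1}, the published hybrid-model settings.
#' @param training_set_id free-text tag stored in the bundle metadata.
#' @return object of class \code{sirna_model}.
#' @export
train_model <- function(records, spec = encoding_spec(),
                        hyperparams = default_hyperparams(),
                        training_set_id = "unnamed") {
  records <- as_sirna_records(records, require_efficacy = TRUE)
  if (nrow(records) < 20L) {
    stop("need at least 20 training records, got ", nrow(records),
         call. = FALSE)
  }
  len <- unique(nchar(records$antisense))
  if (length(len) != 1L) {
    stop("training siRNAs must all have the same length; got ",
         paste(len, collapse = ", "), call. = FALSE)
  }
  hyperparams <- check_hyperparams(hyperparams)
  acc <- if ("accessibility" %in% names(records)) records$accessibility else NULL
  x <- encode_features(records$antisense, spec, accessibility = acc,
                       ids = records$id)
  scaler <- fit_scaler(x, spec$scale_low, spec$scale_high)
  xs <- apply_scaler(x, scaler)
  if (stats::var(records$efficacy) == 0) {
    # every response inside the epsilon tube: the SVR solution is the
    # constant function, which libsvm represents with no support vectors
    warning("all training efficacies are identical; model is degenerate ",
            "and predicts the constant value")
    fit <- NULL
    const <- records$efficacy[1]
  } else {
    fit <- e1071::svm(x = xs, y = records$efficacy,
                      type = "eps-regression", kernel = "radial",
                      gamma = hyperparams$g, cost = hyperparams$c,
                      epsilon = hyperparams$j / 100, scale = FALSE)
    const <- NULL
  }
  structure(list(type = "svr", value = const, spec = spec, scaler = scaler,
                 hyperparams = hyperparams, fit = fit,
                 meta = list(training_set_id = training_set_id,
                             siRNA_length = len,
                             n_train = nrow(records),
                             created_at = format(Sys.time(), tz = "UTC"),
                             format_version = MODEL_FORMAT_VERSION)),
            class = "sirna_model")
}

#' Fixed-prediction model
#'
#' A model bundle that predicts the same efficacy for every sequence of the
#' stated length. Used to inject a known predicted efficacy into the
#' mismatch-efficacy machinery, e.g. in worked examples and tests.
#'
#' @param value the constant predicted efficacy.
#' @param length siRNA length the model accepts (19 or 21).
#' @return object of class \code{sirna_model}.
#' @export
constant_model <- function(value, length = 19L) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  structure(list(type = "constant", value = value,
                 spec = NULL, scaler = NULL, hyperparams = NULL, fit = NULL,
                 meta = list(training_set_id = "constant",
                             siRNA_length = as.integer(length),
                             created_at = format(Sys.time(), tz = "UTC"),
                             format_version = MODEL_FORMAT_VERSION)),
            class = "sirna_model")
}

#' @export
print.sirna_model <- function(x, ...) {
  cat("sirna_model (", x$type, "), siRNA length ", x$meta$siRNA_length, " nt",
      sep = "")
  if (x$type == "svr") {
    cat(sprintf("; trained on %d records [%s]; g=%g c=%g j=%g",
                x$meta$n_train, x$meta$training_set_id,
                x$hyperparams$g, x$hyperparams$c, x$hyperparams$j))
  } else {
    cat(sprintf("; constant prediction %g", x$value))
  }
  cat("\n")
  invisible(x)
}

#' Predict siRNA efficacy
#'
#' @param model a \code{sirna_model}.
#' @param seqs character vector of antisense sequences whose length matches
#'   the model's siRNA length.
#' @param accessibility optional numeric vector (required iff the model's
#'   encoding spec includes the \code{accessibility} encoder).
#' @return numeric vector of predicted efficacies, one per sequence.
#'   Predictions are not clipped to \code{[0, 1]}.
#' @export
predict_efficacy <- function(model, seqs, accessibility = NULL) {
  stopifnot(inherits(model, "sirna_model"))
  if (length(seqs) == 0L) return(numeric(0))
  seqs <- as_rna(seqs)
  bad <- nchar(seqs) != model$meta$siRNA_length
  if (any(bad)) {
    stop("sequence length ", paste(unique(nchar(seqs)[bad]), collapse = ", "),
         " does not match model siRNA length ", model$meta$siRNA_length,
         call. = FALSE)
  }
  if (model$type == "constant" ||
      (model$type == "svr" && is.null(model$fit))) {
    return(rep(model$value, length(seqs)))
  }
  needs_acc <- "accessibility" %in% model$spec$encoders
  if (needs_acc && is.null(accessibility)) {
    stop("model requires a target-site accessibility value per sequence",
         call. = FALSE)
  }
  x <- encode_features(seqs, model$spec,
                       accessibility = if (needs_acc) accessibility else NULL)
  xs <- apply_scaler(x, model$scaler)
  as.numeric(stats::predict(model$fit, xs))
}

#' Regression performance metrics
#'
#' Pearson correlation R, coefficient of determination
#' \code{R2 = 1 - SS_res / SS_tot} (which can be negative), mean absolute
#' error and root mean squared error between predicted and actual efficacy.
#'
#' @param pred,actual numeric vectors of equal nonzero length.
#' @return named list with \code{R}, \code{R2}, \code{MAE}, \code{RMSE},
#'   \code{n}.
#' @export
regression_metrics <- function(pred, actual) {
  if (length(pred) != length(actual) || length(pred) == 0L) {
    stop("pred and actual must have equal nonzero length", call. = FALSE)
  }
  if (any(!is.finite(pred)) || any(!is.finite(actual))) {
    stop("pred and actual must be finite", call. = FALSE)
  }
  err <- actual - pred
  if (stats::var(actual) == 0) {
    warning("actual efficacies have zero variance; R is undefined")
    R <- NaN
  } else if (stats::var(pred) == 0) {
    R <- NaN
  } else {
    R <- stats::cor(pred, actual)
  }
  ss_res <- sum(err^2)
  ss_tot <- sum((actual - mean(actual))^2)
  list(R = R,
       R2 = if (ss_tot == 0) NaN else 1 - ss_res / ss_tot,
       MAE = mean(abs(err)),
       RMSE = sqrt(mean(err^2)),
       n = length(pred))
}

#' Five-fold cross-validation of the SVR model
#'
#' Randomly partitions the records into \code{folds} sets, trains on
#' \code{folds - 1} of them (re-fitting the feature scaler inside each
#' training fold, so no information leaks from held-out rows) and predicts
#' the remaining set, rotating until every record has been tested exactly
#' once. Headline metrics are pooled over the concatenated held-out
#' predictions; per-fold metrics are also reported.
#'
#' @inheritParams train_model
#' @param folds number of folds (default 5).
#' @param seed integer seed controlling the fold assignment (default 42).
#' @return list of class \code{sirna_cv} with elements \code{pooled}
#'   (metrics list), \code{per_fold} (data frame), \code{predictions}
#'   (data frame with id, fold, actual, predicted), \code{folds},
#'   \code{seed}.
#' @export
crossval <- function(records, spec = encoding_spec(),
                     hyperparams = default_hyperparams(),
                     folds = 5L, seed = 42L) {
  records <- as_sirna_records(records, require_efficacy = TRUE)
  folds <- as.integer(folds)
  if (is.na(folds) || folds < 2L) stop("folds must be >= 2", call. = FALSE)
  n <- nrow(records)
  if (n < folds * 5L) {
    stop("need at least ", folds * 5L, " records for ", folds,
         "-fold cross-validation", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  assignment <- sample(rep_len(seq_len(folds), n))

  preds <- numeric(n)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_idx <- which(assignment == f)
    fit <- train_model(records[-test_idx, , drop = FALSE], spec, hyperparams,
                       training_set_id = sprintf("cv_fold_%d", f))
    acc <- if ("accessibility" %in% names(records)) {
      records$accessibility[test_idx]
    } else NULL
    p <- predict_efficacy(fit, records$antisense[test_idx], accessibility = acc)
    preds[test_idx] <- p
    m <- regression_metrics(p, records$efficacy[test_idx])
    per_fold[[f]] <- data.frame(fold = f, R = m$R, R2 = m$R2,
                                MAE = m$MAE, RMSE = m$RMSE, n = m$n)
  }
  structure(list(pooled = regression_metrics(preds, records$efficacy),
                 per_fold = do.call(rbind, per_fold),
                 predictions = data.frame(id = records$id,
                                          fold = assignment,
                                          actual = records$efficacy,
                                          predicted = preds,
                                          stringsAsFactors = FALSE),
                 folds = folds, seed = seed),
            class = "sirna_cv")
}

#' @export
print.sirna_cv <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "%d-fold CV (seed %d, n = %d): pooled R = %.3f, R2 = %.3f, MAE = %.3f, RMSE = %.3f\n",
    x$folds, x$seed, p$n, p$R, p$R2, p$MAE, p$RMSE))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Save / load a model bundle
#'
#' The bundle is written as a single archive (an RDS container) holding a
#' JSON metadata block and the serialized regressor state. The loader
#' validates the format-version field and errors on mismatch. Metadata
#' round-trips bit-identically through the JSON block.
#'
#' @param model a \code{sirna_model}.
#' @param path file path for the archive.
#' @return \code{save_model} returns \code{path} invisibly;
#'   \code{load_model} returns the restored \code{sirna_model}.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sirna_model"))
  archive <- list(
    meta_json = jsonlite::toJSON(model$meta, auto_unbox = TRUE, digits = NA),
    type = model$type,
    value = model$value,
    spec = model$spec,
    scaler = model$scaler,
    hyperparams = model$hyperparams,
    fit = model$fit
  )
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  archive <- readRDS(path)
  meta <- jsonlite::fromJSON(archive$meta_json)
  if (is.null(meta$format_version) ||
      meta$format_version != MODEL_FORMAT_VERSION) {
    stop("unsupported model format version: ",
         if (is.null(meta$format_version)) "missing" else meta$format_version,
         call. = FALSE)
  }
  structure(list(type = archive$type, value = archive$value,
                 spec = archive$spec, scaler = archive$scaler,
                 hyperparams = archive$hyperparams, fit = archive$fit,
                 meta = meta),
            class = "sirna_model")
}
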