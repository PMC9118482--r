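#' @include AllClasses.R combine.R ffnn.R evaluate.R
NULL

#' Default hyperparameter grid for the meta-model
#'
#' Window sizes \{1, 3, 5, 7\} crossed with hidden-layer layouts (6),
#' (6, 4) and (6, 4, 2) — nested widths of depth 1 to 3, the deepest being
#' the published-model architecture for this kind of meta-predictor.
#'
#' @return list of configs, each with `window` and `hidden`.
#' @export
defaultMetaGrid <- function() {
  out <- list()
  for (w in c(1L, 3L, 5L, 7L))
    for (hid in list(6L, c(6L, 4L), c(6L, 4L, 2L)))
      out[[length(out) + 1L]] <- list(window = w, hidden = hid)
  out
}

## Assemble pooled windowed design matrix and labels for one split.
## Eligible records follow the pooling convention of poolResidues().
.metaDesign <- function(ds, task, norm, window) {
  Xs <- list()
  ys <- list()
  for (rec in records(ds)) {
    lab <- .recordPoolLabels(rec, task)
    if (is.null(lab)) next
    dtr <- rec@predictions[[paste0(task, "_disorder_trained")]]
    str <- rec@predictions[[paste0(task, "_structure_trained")]]
    if (is.null(dtr) || is.null(str))
      stop("record ", rec@id, ": missing input propensity track")
    a <- applyNormalizer(dtr, norm$disorder_trained)
    b <- applyNormalizer(str, norm$structure_trained)
    M <- .windowMatrix(a, b, window)
    keep <- !is.na(lab)
    Xs[[length(Xs) + 1L]] <- M[keep, , drop = FALSE]
    ys[[length(ys) + 1L]] <- lab[keep]
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys, use.names = FALSE)
  if (is.null(X) || !any(y == 1L) || !any(y == 0L))
    stop("split lacks positive or negative residues for task ", task)
  list(X = X, y = as.numeric(y))
}

#' Train the windowed feed-forward meta-model
#'
#' Fits one network per grid configuration on the training split (all
#' eligible residues pooled across proteins, inputs min-max normalized with
#' parameters fitted on the training split only) and returns the
#' configuration with the maximal validation-split AUC; exact AUC ties are
#' broken toward the smaller window, then the shallower network. Training
#' uses class-weighted binary cross-entropy, Adam mini-batch updates and
#' early stopping on validation AUC; all randomness (weight initialization,
#' batch shuffling) derives from `seed`, so identical inputs and seed give
#' byte-identical weights.
#'
#' @param train,validation [TrackDataset-class] splits; both must contain
#'   positive and negative residues for the task.
#' @param task `"dna"` or `"rna"`.
#' @param grid list of configs as from [defaultMetaGrid()].
#' @param seed integer seed for all training randomness.
#' @param epochs epoch cap per configuration.
#' @param batch mini-batch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation-AUC
#'   improvement).
#' @return a [MetaModel-class] whose `validationAuc` slot records the
#'   selected configuration's validation AUC.
#' @seealso [predictMeta()], [writeMetaModel()]
#' @export
trainMeta <- function(train, validation, task = c("dna", "rna"),
                      grid = defaultMetaGrid(), seed = 1L,
                      epochs = 100L, batch = 256L, lr = 0.005,
                      patience = 10L) {
  task <- match.arg(task)
  stopifnot(length(grid) >= 1L)
  norm <- fitNormalizer(train, task)
  windows <- unique(vapply(grid, `[[`, integer(1), "window"))
  designs <- lapply(windows, function(w)
    list(train = .metaDesign(train, task, norm, w),
         val = .metaDesign(validation, task, norm, w)))
  names(designs) <- as.character(windows)

  fits <- lapply(grid, function(cfg) {
    d <- designs[[as.character(cfg$window)]]
    withr::with_seed(seed,
      .ffTrain(d$train$X, d$train$y, d$val$X, d$val$y, cfg$hidden,
               epochs = epochs, batch = batch, lr = lr,
               patience = patience))
  })
  aucs <- vapply(fits, `[[`, numeric(1), "valAuc")
  wins <- vapply(grid, `[[`, integer(1), "window")
  depths <- vapply(grid, function(cfg) length(cfg$hidden), integer(1))
  best <- order(-aucs, wins, depths)[1]

  cfg <- grid[[best]]
  new("MetaModel", task = task,
      config = list(window = cfg$window, hidden = as.integer(cfg$hidden),
                    seed = as.integer(seed), epochs = as.integer(epochs),
                    batch = as.integer(batch), lr = lr,
                    patience = as.integer(patience),
                    epochs_run = fits[[best]]$epochsRun),
      weights = fits[[best]]$net, norm = norm,
      validationAuc = aucs[best])
}

#' Predict per-residue binding propensities with a meta-model
#'
#' Normalizes the record's two input propensity tracks with the model's
#' stored parameters, extracts sliding-window features and runs the network
#' forward. Output depends only on the record's own tracks.
#'
#' @param model a [MetaModel-class].
#' @param rec a [ProteinRecord-class] carrying both input tracks for the
#'   model's task.
#' @return numeric propensity track in \[0, 1\], one value per residue.
#' @export
predictMeta <- function(model, rec) {
  stopifnot(is(model, "MetaModel"), is(rec, "ProteinRecord"))
  task <- model@task
  dtr <- rec@predictions[[paste0(task, "_disorder_trained")]]
  str <- rec@predictions[[paste0(task, "_structure_trained")]]
  if (is.null(dtr) || is.null(str))
    stop("record ", rec@id, ": missing input track for meta prediction")
  a <- applyNormalizer(dtr, model@norm$disorder_trained)
  b <- applyNormalizer(str, model@norm$structure_trained)
  X <- .windowMatrix(a, b, model@config$window)
  .ffForward(model@weights, X)
}

#' Attach meta-model predictions to every eligible record of a dataset
#'
#' Stores [predictMeta()] output as the `dna_meta`/`rna_meta` track of each
#' record that carries both input tracks.
#'
#' @param ds a [TrackDataset-class].
#' @param model a [MetaModel-class].
#' @return the dataset with meta tracks filled in.
#' @export
addMetaTrack <- function(ds, model) {
  key <- paste0(model@task, "_meta")
  recs <- lapply(records(ds), function(rec) {
    p <- rec@predictions
    if (is.null(p[[paste0(model@task, "_disorder_trained")]]) ||
        is.null(p[[paste0(model@task, "_structure_trained")]]))
      return(rec)
    p[[key]] <- predictMeta(model, rec)
    rec@predictions <- p
    rec
  })
  initialize(ds, records = recs)
}

#' Serialize a meta-model to JSON
#'
#' Writes the configuration, normalization parameters and layer weights as
#' a plain JSON document readable by [readMetaModel()].
#'
#' @param model a [MetaModel-class].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeMetaModel <- function(model, path) {
  obj <- list(task = model@task, config = model@config,
              norm = list(
                disorder_trained = as.numeric(model@norm$disorder_trained),
                structure_trained = as.numeric(model@norm$structure_trained)),
              weights = list(W = lapply(model@weights$W, unclass),
                             b = model@weights$b),
              validation_auc = model@validationAuc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname writeMetaModel
#' @export
readMetaModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  normVec <- function(v) {
    out <- c(min = v[1], max = v[2])
    attr(out, "degenerate") <- out[1] == out[2]
    out
  }
  cfg <- obj$config
  cfg$window <- as.integer(cfg$window)
  cfg$hidden <- as.integer(cfg$hidden)
  W <- lapply(obj$weights$W, function(w) {
    if (is.matrix(w)) w else matrix(unlist(w), nrow = length(w), byrow = TRUE)
  })
  b <- obj$weights$b
  if (!is.list(b)) b <- list(b)
  b <- lapply(b, as.numeric)
  new("MetaModel", task = obj$task, config = cfg,
      weights = list(W = W, b = b),
      norm = list(task = obj$task,
                  disorder_trained = normVec(obj$norm$disorder_trained),
                  structure_trained = normVec(obj$norm$structure_trained)),
      validationAuc = as.numeric(obj$validation_auc))
}
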