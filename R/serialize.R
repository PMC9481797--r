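#' @title Model archive input/output
#' @description A fitted ensemble is stored as a directory of plain-text
#'   matrix files plus JSON metadata, so fitting and prediction can run in
#'   separate command-line invocations.
#' @name serialize
NULL

write_mat <- function(M, path)
  utils::write.table(M, path, row.names = FALSE, col.names = FALSE, sep = "\t")

read_mat <- function(path) {
  M <- as.matrix(utils::read.table(path))
  dimnames(M) <- NULL
  M
}

#' Save a fitted ensemble model to a directory
#'
#' @param model an `ensemble_model`.
#' @param dir target directory (created; one subdirectory per band).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "ensemble_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$config
  meta <- list(bands = cfg$bands, cost = cfg$cost,
               balanced_weights = cfg$balanced_weights, d = cfg$d,
               vote_threshold = cfg$vote_threshold, align = cfg$align,
               strict_subjects = cfg$strict_subjects,
               karcher_tol = cfg$karcher_tol,
               karcher_max_iter = cfg$karcher_max_iter,
               ridge_factor = cfg$ridge_factor)
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (bn in names(model$band_models)) {
    bm <- model$band_models[[bn]]
    bd <- file.path(dir, bn)
    dir.create(bd, showWarnings = FALSE)
    emb <- bm$embedding
    write_mat(emb$eigenvectors, file.path(bd, "eigenvectors.tsv"))
    for (i in seq_along(bm$train_scms))
      write_mat(bm$train_scms[[i]], file.path(bd, sprintf("scm_%04d.tsv", i)))
    if (!is.null(bm$subject_means))
      for (s in names(bm$subject_means$mean))
        write_mat(bm$subject_means$mean[[s]],
                  file.path(bd, paste0("mean_", s, ".tsv")))
    jsonlite::write_json(list(
      subjects = as.list(names(bm$subject_means$mean)),
      n_train = length(bm$train_scms),
      eigenvalues = emb$eigenvalues, row_means = emb$row_means,
      grand_mean = emb$grand_mean, ids = emb$ids, d = emb$d,
      neg_mass = emb$neg_mass,
      w = bm$classifier$w, b = bm$classifier$b),
      file.path(bd, "band.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Load an ensemble model saved by [save_ensemble()]
#'
#' @param dir archive directory.
#' @return an `ensemble_model`.
#' @export
load_ensemble <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "config.json"))
  cfg <- decoder_config(
    bands = as.data.frame(meta$bands), cost = meta$cost,
    balanced_weights = meta$balanced_weights,
    d = if (identical(meta$d, "auto")) "auto" else as.integer(meta$d),
    vote_threshold = meta$vote_threshold, align = meta$align,
    strict_subjects = meta$strict_subjects, karcher_tol = meta$karcher_tol,
    karcher_max_iter = meta$karcher_max_iter,
    ridge_factor = meta$ridge_factor)
  band_models <- lapply(seq_len(nrow(cfg$bands)), function(b) {
    bn <- cfg$bands$name[b]
    bd <- file.path(dir, bn)
    bj <- jsonlite::fromJSON(file.path(bd, "band.json"))
    scms <- lapply(seq_len(bj$n_train), function(i)
      read_mat(file.path(bd, sprintf("scm_%04d.tsv", i))))
    sm <- NULL
    if (length(bj$subjects) > 0) {
      means <- lapply(bj$subjects, function(s)
        read_mat(file.path(bd, paste0("mean_", s, ".tsv"))))
      names(means) <- bj$subjects
      sm <- structure(list(
        mean = means,
        invsqrt = lapply(means, spd_invsqrt),
        global_mean = karcher_mean(means, tol = cfg$karcher_tol,
                                   max_iter = cfg$karcher_max_iter)
      ), class = "subject_means")
    }
    emb <- structure(list(
      coords = read_mat(file.path(bd, "eigenvectors.tsv")) %*%
        diag(sqrt(bj$eigenvalues), length(bj$eigenvalues)),
      eigenvalues = bj$eigenvalues,
      eigenvectors = read_mat(file.path(bd, "eigenvectors.tsv")),
      row_means = bj$row_means, grand_mean = bj$grand_mean,
      ids = bj$ids, d = bj$d, neg_mass = bj$neg_mass
    ), class = "mds_embedding")
    structure(list(band = cfg$bands[b, ], subject_means = sm,
                   embedding = emb, train_scms = scms,
                   classifier = list(w = bj$w, b = bj$b)),
              class = "band_model")
  })
  names(band_models) <- cfg$bands$name
  structure(list(band_models = band_models, config = cfg,
                 classes = c(0L, 1L)),
            class = "ensemble_model")
}
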