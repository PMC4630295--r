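face_neighbors <- function(ijk, dims) {
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  nb <- sweep(offs, 2, ijk, "+")
  keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
    nb[, 2] >= 1 & nb[, 2] <= dims[2] &
    nb[, 3] >= 1 & nb[, 3] <= dims[3]
  nb[keep, , drop = FALSE]
}

#' Whole-volume vein suppression with split-run estimation
#'
#' For every in-mask voxel, estimates the suppression model on the training
#' run and applies it to the test run (pass the same series twice for
#' same-run estimation, as in the simulation grid). With `method = "sPR"`
#' and `neighborhood = 7`, the phase source is chosen among the voxel itself
#' and its six face-adjacent voxels (boundary voxels use their truncated
#' neighbourhoods); `neighborhood = 1` restricts to the voxel's own phase.
#' With `method = "PR"` the closed-form chi-squared fit of the voxel's own
#' phase is used. Degenerate voxels (flagged in either run's mask, or with a
#' constant training series) are passed through unsuppressed and flagged.
#'
#' @param train,test Preprocessed (z-scored) [complex_volume_series()] of
#'   identical dimension.
#' @param method `"sPR"` (default) or `"PR"`.
#' @param neighborhood 7 (self + six face-adjacent, default) or 1. Ignored
#'   for PR.
#' @param coefficients Passed to [fit_pr_chisq()] when `method = "PR"`.
#' @return A list of class `suppressed_volume`: `suppressed` (4D array, the
#'   vein-suppressed magnitude series of the test run, z-score units),
#'   `fits` (tibble: voxel indices, source offset, `estimate` (correlation
#'   or b1*), `flag`) and `method`.
#' @export
suppress_volume <- function(train, test, method = c("sPR", "PR"),
                            neighborhood = 7,
                            coefficients = c("minimizer", "printed")) {
  method <- match.arg(method)
  coefficients <- match.arg(coefficients)
  if (!identical(dim(train$magnitude), dim(test$magnitude))) {
    stop_data("train and test series must share shape")
  }
  if (!neighborhood %in% c(1, 7)) stop_config("`neighborhood` must be 1 or 7")
  if (!isTRUE(train$zscored) || !isTRUE(test$zscored)) {
    warn("suppress_volume expects preprocessed (z-scored) series")
  }
  d <- dim(train$magnitude)
  dims <- d[1:3]
  bad <- (train$mask %||% array(FALSE, dims)) | (test$mask %||% array(FALSE, dims))
  out <- test$magnitude
  rows <- vector("list", prod(dims))
  nrow_used <- 0L
  for (k in seq_len(dims[3])) {
    for (j in seq_len(dims[2])) {
      for (i in seq_len(dims[1])) {
        ijk <- c(i, j, k)
        nrow_used <- nrow_used + 1L
        if (bad[i, j, k]) {
          rows[[nrow_used]] <- list(i, j, k, NA_integer_, NA_integer_, NA_integer_,
                                    NA_real_, "degenerate")
          next
        }
        Sm_tr <- train$magnitude[i, j, k, ]
        if (sd(Sm_tr) == 0) {
          rows[[nrow_used]] <- list(i, j, k, NA_integer_, NA_integer_, NA_integer_,
                                    NA_real_, "degenerate")
          next
        }
        if (method == "PR") {
          Sp_tr <- train$phase[i, j, k, ]
          if (sd(Sp_tr) == 0) {
            rows[[nrow_used]] <- list(i, j, k, NA_integer_, NA_integer_, NA_integer_,
                                      NA_real_, "degenerate")
            next
          }
          fit <- fit_pr_chisq(Sm_tr, Sp_tr, coefficients = coefficients)
          out[i, j, k, ] <- apply_pr(test$magnitude[i, j, k, ],
                                     test$phase[i, j, k, ], fit)
          rows[[nrow_used]] <- list(i, j, k, 0L, 0L, 0L, fit$b1_star, fit$flag)
        } else {
          cand <- if (neighborhood == 7) {
            rbind(ijk, face_neighbors(ijk, dims))
          } else {
            matrix(ijk, nrow = 1)
          }
          ok <- !bad[cand]
          cand <- cand[ok, , drop = FALSE]
          phases <- lapply(seq_len(nrow(cand)), function(q) {
            train$phase[cand[q, 1], cand[q, 2], cand[q, 3], ]
          })
          usable <- vapply(phases, sd, numeric(1)) > 0
          if (!any(usable)) {
            rows[[nrow_used]] <- list(i, j, k, NA_integer_, NA_integer_, NA_integer_,
                                      NA_real_, "degenerate")
            next
          }
          cand <- cand[usable, , drop = FALSE]
          phases <- phases[usable]
          fit <- fit_spr(Sm_tr, phases, self = 1L)
          src <- cand[fit$source_index, ]
          out[i, j, k, ] <- apply_spr(test$magnitude[i, j, k, ],
                                      test$phase[src[1], src[2], src[3], ],
                                      fit)
          rows[[nrow_used]] <- list(i, j, k, src[1] - i, src[2] - j, src[3] - k,
                                    fit$correlation, "ok")
        }
      }
    }
  }
  fits <- tibble(
    x = vapply(rows, `[[`, integer(1), 1),
    y = vapply(rows, `[[`, integer(1), 2),
    z = vapply(rows, `[[`, integer(1), 3),
    dx = vapply(rows, function(r) as.integer(r[[4]]), integer(1)),
    dy = vapply(rows, function(r) as.integer(r[[5]]), integer(1)),
    dz = vapply(rows, function(r) as.integer(r[[6]]), integer(1)),
    estimate = vapply(rows, `[[`, numeric(1), 7),
    flag = vapply(rows, `[[`, character(1), 8)
  )
  structure(
    list(suppressed = out, fits = fits, method = method,
         neighborhood = neighborhood,
         sample_interval = test$sample_interval,
         voxel_size = test$voxel_size),
    class = "suppressed_volume"
  )
}

#' @export
print.suppressed_volume <- function(x, ...) {
  d <- dim(x$suppressed)
  cat(sprintf(
    "<suppressed_volume> %s (neighbourhood %d): %d x %d x %d x %d, %d voxels flagged\n",
    x$method, x$neighborhood, d[1], d[2], d[3], d[4],
    sum(x$fits$flag != "ok")
  ))
  invisible(x)
}

#' @export
tidy.suppressed_volume <- function(x, ...) x$fits
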