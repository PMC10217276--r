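#' Minority-class oversampling by synthetic interpolation (SMOTE)
#'
#' For every class with multiplier \eqn{f > 1}, adds \eqn{(f-1) \times}
#' class-size synthetic rows, each \eqn{x_{new} = x_i + u (x_{nn} - x_i)}
#' with \eqn{u \sim U[0,1]} and \eqn{x_{nn}} one of the \eqn{k} nearest
#' same-class neighbours (Euclidean). Original rows are retained unchanged
#' and synthetic rows inherit their parent's grade, so class counts after
#' augmentation are exactly multiplier times the original size. The default
#' multipliers (3, 1, 4) for grades (1, 2, 3) turn a 22/71/7 cohort into the
#' balanced 66/71/28 = 165-sample table used for classifier training.
#'
#' @param features Numeric matrix (samples x variables), e.g. PCA scores.
#' @param grades Integer class labels per row.
#' @param multipliers Named or positional integer factors (>= 1) per grade
#'   level (sorted unique grades).
#' @param k_neighbors Neighbour pool size; automatically reduced to class
#'   size minus one for tiny classes.
#' @param seed Integer seed; output is deterministic per seed.
#' @param extra Optional numeric vector (e.g. SSC in \eqn{^\circ}Brix)
#'   interpolated alongside the features with the same \eqn{u}, for
#'   regression augmentation.
#' @return \code{list(features, grades, extra, synthetic)} where
#'   \code{synthetic} flags the interpolated rows.
#' @export
smote <- function(features, grades, multipliers = c(3L, 1L, 4L),
                  k_neighbors = 5L, seed = 1L, extra = NULL) {
  features <- as.matrix(features)
  grades <- as.integer(grades)
  stopifnot(nrow(features) == length(grades), k_neighbors >= 1,
            all(multipliers >= 1))
  if (!is.null(extra)) stopifnot(length(extra) == length(grades))
  levels <- sort(unique(grades))
  multipliers <- rep_len(as.integer(multipliers), length(levels))
  new_feat <- list()
  new_grade <- integer(0)
  new_extra <- numeric(0)
  with_seed(seed, {
    for (li in seq_along(levels)) {
      f <- multipliers[li]
      if (f == 1L) next
      members <- which(grades == levels[li])
      if (length(members) < 2L) {
        stop(sprintf("cannot oversample grade %d: only %d member(s)",
                     levels[li], length(members)))
      }
      k_eff <- min(k_neighbors, length(members) - 1L)
      sub <- features[members, , drop = FALSE]
      d <- as.matrix(stats::dist(sub))
      diag(d) <- Inf
      n_syn <- (f - 1L) * length(members)
      parent <- rep_len(seq_along(members), n_syn)
      rows <- matrix(NA_real_, n_syn, ncol(features))
      ext <- numeric(n_syn)
      for (s in seq_len(n_syn)) {
        i <- parent[s]
        nn_pool <- order(d[i, ])[seq_len(k_eff)]
        j <- nn_pool[sample.int(k_eff, 1L)]
        u <- stats::runif(1)
        rows[s, ] <- sub[i, ] + u * (sub[j, ] - sub[i, ])
        if (!is.null(extra)) {
          ext[s] <- extra[members[i]] + u * (extra[members[j]] - extra[members[i]])
        }
      }
      new_feat[[length(new_feat) + 1L]] <- rows
      new_grade <- c(new_grade, rep(levels[li], n_syn))
      if (!is.null(extra)) new_extra <- c(new_extra, ext)
    }
  })
  syn <- if (length(new_feat)) do.call(rbind, new_feat) else
    matrix(numeric(0), 0, ncol(features))
  list(features = rbind(features, syn),
       grades = c(grades, new_grade),
       extra = if (!is.null(extra)) c(extra, new_extra),
       synthetic = c(rep(FALSE, length(grades)), rep(TRUE, nrow(syn))))
}
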