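# Repeated random half-split EFA/CFA stability procedure for deriving
# data-driven dietary patterns. For each repeat, participants are split
# 50/50; EFA (ML + oblimin) on one half proposes, for every factor count k,
# structures of foods with |loading| > loading_thresh; CFA on the other half
# re-estimates them and yields fit indices. Factors are then matched across
# repeats and across k within the fit plateau by Tucker congruence; only
# constructs reproduced in every repeat become patterns.

#' Derive stable data-driven dietary patterns
#'
#' @param data Participants x foods matrix of frequencies/day (rownames used
#'   as participant ids when present).
#' @param k_range Inclusive range of factor counts to scan (default 2:18;
#'   infeasible counts for the food set are clipped with a message).
#' @param n_rep Number of random half-split repeats (default 5).
#' @param loading_thresh Absolute EFA loading above which a food enters a
#'   factor's CFA structure (default 0.3).
#' @param phi_thresh Tucker congruence at or above which two factors count
#'   as the same construct (default 0.85).
#' @param plateau_tol Composite-fitness tolerance defining the plateau of k
#'   values whose factors are pooled for matching (default 0.01 on the mean
#'   of CFI, TLI, 1 - RMSEA, 1 - SRMR).
#' @param seed Integer seed for the half-splits (mandatory).
#' @return A `pattern_set`: list with `patterns` (each: name, foods, signed
#'   loadings, reproducibility count), `n_stable`, `fitness` (per-k averaged
#'   fit indices, rank-average and composite), `plateau`, `k_best`,
#'   `final_fit` (CFA of the stable patterns on all participants; `NULL` if
#'   none), `scores` (participant x pattern data frame), and `settings`. An
#'   empty pattern set is a valid result, not an error.
#' @export
stability_select <- function(data, k_range = 2:18, n_rep = 5,
                             loading_thresh = 0.3, phi_thresh = 0.85,
                             plateau_tol = 0.01, seed = NULL) {
  seed <- check_seed(seed)
  if (n_rep < 2L) stop("n_rep must be >= 2")
  data <- as.matrix(data)
  n <- nrow(data)
  p <- ncol(data)
  if (is.null(colnames(data))) colnames(data) <- sprintf("V%02d", seq_len(p))
  feasible <- k_range[((p - k_range)^2 - p - k_range) / 2 >= 0 & k_range < p]
  if (!length(feasible)) stop("no feasible factor counts in k_range")
  if (length(feasible) < length(k_range))
    message("clipping k_range to feasible counts ", min(feasible), "..",
            max(feasible), " for ", p, " foods")
  set.seed(seed)

  runs <- list()   # one entry per (rep, k) CFA solution
  fitrows <- list()
  for (r in seq_len(n_rep)) {
    half1 <- sort(sample.int(n, floor(n / 2)))
    half2 <- setdiff(seq_len(n), half1)
    for (k in feasible) {
      sol <- tryCatch(suppressWarnings(efa_ml(data[half1, , drop = FALSE], k)),
                      error = function(e) NULL)
      if (is.null(sol)) next
      struct <- list()
      for (j in seq_len(k)) {
        foods <- colnames(data)[abs(sol$loadings[, j]) > loading_thresh]
        if (length(foods) >= 2L) struct[[paste0("F", j)]] <- foods
      }
      struct <- struct[!duplicated(lapply(struct, sort))]
      if (!length(struct)) next
      cf <- tryCatch(suppressWarnings(
        cfa_fit(data[half2, , drop = FALSE], struct)),
        error = function(e) NULL)
      if (is.null(cf) || !cf$converged) next
      vecs <- matrix(0, p, length(struct),
                     dimnames = list(colnames(data), names(struct)))
      vecs[rownames(cf$loadings), ] <- cf$loadings
      runs[[length(runs) + 1L]] <- list(rep = r, k = k, vecs = vecs)
      fitrows[[length(fitrows) + 1L]] <-
        data.frame(rep = r, k = k, cfi = cf$fit["cfi"], tli = cf$fit["tli"],
                   rmsea = cf$fit["rmsea"], srmr = cf$fit["srmr"],
                   row.names = NULL)
    }
  }

  settings <- list(k_range = feasible, n_rep = n_rep,
                   loading_thresh = loading_thresh, phi_thresh = phi_thresh,
                   plateau_tol = plateau_tol, seed = seed)
  empty <- function(fitness) {
    out <- list(patterns = list(), n_stable = 0L, fitness = fitness,
                plateau = integer(), k_best = NA_integer_, final_fit = NULL,
                scores = NULL, settings = settings)
    class(out) <- "pattern_set"
    out
  }
  if (!length(runs)) return(empty(NULL))

  fitdf <- do.call(rbind, fitrows)
  fitness <- stats::aggregate(fitdf[c("cfi", "tli", "rmsea", "srmr")],
                              by = list(k = fitdf$k), FUN = mean)
  # combined assessment of the averaged fitness measures: rank-average
  # (higher CFI/TLI better, lower RMSEA/SRMR better) picks the best k; the
  # plateau is defined on the composite goodness scale
  rk <- cbind(rank(-fitness$cfi), rank(-fitness$tli),
              rank(fitness$rmsea), rank(fitness$srmr))
  fitness$rank_avg <- rowMeans(rk)
  fitness$composite <- (fitness$cfi + fitness$tli +
                          (1 - fitness$rmsea) + (1 - fitness$srmr)) / 4
  k_best <- fitness$k[which.min(fitness$rank_avg)]
  plateau <- fitness$k[fitness$composite >=
                         max(fitness$composite) - plateau_tol]

  # pool factors from all repeats and plateau ks, then cluster greedily by
  # Tucker congruence with sign alignment
  pool <- list()
  for (run in runs) {
    if (!(run$k %in% plateau)) next
    for (j in seq_len(ncol(run$vecs)))
      pool[[length(pool) + 1L]] <- list(rep = run$rep, k = run$k,
                                        v = run$vecs[, j])
  }
  if (!length(pool)) return(empty(fitness))

  assigned <- logical(length(pool))
  clusters <- list()
  for (i in seq_along(pool)) {
    if (assigned[i]) next
    members <- list(pool[[i]])
    assigned[i] <- TRUE
    for (j in seq_along(pool)) {
      if (assigned[j]) next
      ph <- tucker_phi(pool[[i]]$v, pool[[j]]$v)
      if (abs(ph) >= phi_thresh) {
        m <- pool[[j]]
        if (ph < 0) m$v <- -m$v
        members[[length(members) + 1L]] <- m
        assigned[j] <- TRUE
      }
    }
    clusters[[length(clusters) + 1L]] <- members
  }
  # merge clusters whose mean loading vectors still agree
  reps_of <- function(cl) sort(unique(vapply(cl, `[[`, 0, "rep")))
  mean_vec <- function(cl) rowMeans(vapply(cl, `[[`, numeric(p), "v"))
  merged <- TRUE
  while (merged && length(clusters) > 1L) {
    merged <- FALSE
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        ph <- tucker_phi(mean_vec(clusters[[a]]), mean_vec(clusters[[b]]))
        if (abs(ph) >= phi_thresh) {
          cb <- clusters[[b]]
          if (ph < 0) cb <- lapply(cb, function(m) { m$v <- -m$v; m })
          clusters[[a]] <- c(clusters[[a]], cb)
          clusters[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
  }

  stable <- Filter(function(cl) length(reps_of(cl)) == n_rep, clusters)
  if (!length(stable)) return(empty(fitness))
  # order by reproducibility, then by loading mass
  counts <- vapply(stable, length, 0L)
  mass <- vapply(stable, function(cl) sum(mean_vec(cl)^2), 0)
  stable <- stable[order(-counts, -mass)]

  patterns <- lapply(seq_along(stable), function(i) {
    v <- mean_vec(stable[[i]])
    foods <- colnames(data)[abs(v) > loading_thresh]
    if (length(foods) < 2L)
      foods <- colnames(data)[order(-abs(v))[1:2]]
    list(name = sprintf("pattern_%d", i), foods = foods,
         loadings = v[foods], full_loadings = v,
         reproducibility = length(stable[[i]]))
  })
  names(patterns) <- vapply(patterns, `[[`, "", "name")

  final_struct <- lapply(patterns, `[[`, "foods")
  final_fit <- tryCatch(suppressWarnings(cfa_fit(data, final_struct)),
                        error = function(e) NULL)
  scores <- if (!is.null(final_fit))
    extract_scores(final_fit, participant_id = rownames(data)) else NULL

  out <- list(patterns = patterns, n_stable = length(patterns),
              fitness = fitness, plateau = plateau, k_best = k_best,
              final_fit = final_fit, scores = scores, settings = settings)
  class(out) <- "pattern_set"
  out
}

#' @export
print.pattern_set <- function(x, ...) {
  if (!x$n_stable) {
    cat("pattern_set: no stable patterns reproduced across all",
        x$settings$n_rep, "half-splits\n")
    return(invisible(x))
  }
  cat("pattern_set:", x$n_stable, "stable dietary pattern(s)",
      "(", x$settings$n_rep, "half-splits, k in",
      paste(range(x$settings$k_range), collapse = ".."), ")\n")
  for (pt in x$patterns)
    cat("  ", pt$name, " [x", pt$reproducibility, "]: ",
        paste(pt$foods, collapse = ", "), "\n", sep = "")
  invisible(x)
}
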