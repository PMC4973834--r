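# Reconstruction of participant-level data from cumulative 2x2 tables at
# ordered cut-points, and bootstrap estimation of the within-study
# correlation between the log odds ratios at different cut-points.

validate_tables <- function(tables) {
  tables <- as_tibble(tables)
  need <- c("cutpoint", "a", "b", "c", "d")
  miss <- setdiff(need, names(tables))
  if (length(miss)) abort(paste0("2x2 table input missing column '", miss[1], "'"))
  if (nrow(tables) == 0L) abort("no 2x2 tables supplied")
  cnt <- as.matrix(tables[c("a", "b", "c", "d")])
  if (any(cnt < 0) || any(cnt != round(cnt))) abort("cell counts must be non-negative integers")
  tables <- tables[order(tables$cutpoint), ]
  if (anyDuplicated(tables$cutpoint)) abort("duplicate cut-point in 2x2 tables")
  tot_e <- tables$a + tables$c
  tot_n <- tables$b + tables$d
  if (length(unique(tot_e)) > 1L || length(unique(tot_n)) > 1L) {
    abort("tables are inconsistent: event and non-event totals differ across cut-points (not the same cohort)")
  }
  if (tot_e[1] + tot_n[1] <= 0) abort("empty cohort")
  tables
}

#' Interval counts from cumulative 2x2 tables at ordered cut-points
#'
#' For a single cohort dichotomised at several ordered cut-points, each
#' 2x2 table gives the events (`a`) and non-events (`b`) with factor value
#' at or below the cut-point, and the events (`c`) and non-events (`d`)
#' above it. Because the tables are cumulative in the cut-point, successive
#' differencing of the below-cut-point margins recovers the number of
#' events and non-events falling in each interval between adjacent
#' cut-points — which is exactly the participant-level information needed
#' to bootstrap the joint distribution of the log odds ratios.
#'
#' @param tables A data frame with columns `cutpoint`, `a`, `b`, `c`, `d`
#'   (one row per cut-point, same cohort).
#' @return A tibble with one row per interval (the last interval is above
#'   the largest cut-point): `interval`, `upper` (upper cut-point, `Inf`
#'   for the last), `events`, `nonevents`.
#' @export
#' @examples
#' tables_to_intervals(data.frame(cutpoint = 5, a = 10, b = 20, c = 5, d = 65))
tables_to_intervals <- function(tables) {
  tables <- validate_tables(tables)
  cum_e <- tables$a
  cum_n <- tables$b
  tot_e <- tables$a[1] + tables$c[1]
  tot_n <- tables$b[1] + tables$d[1]
  de <- diff(c(0, cum_e, tot_e))
  dn <- diff(c(0, cum_n, tot_n))
  if (any(de < 0) || any(dn < 0)) {
    i <- which(de < 0 | dn < 0)[1]
    pair <- if (i <= 1L) {
      as.character(tables$cutpoint[1])
    } else {
      paste(tables$cutpoint[min(i - 1L, nrow(tables))], "->",
        tables$cutpoint[min(i, nrow(tables))])
    }
    abort(paste0(
      "inconsistent 2x2 tables: counts below the cut-point decrease between cut-points ",
      pair
    ))
  }
  tibble(
    interval = seq_along(de),
    upper = c(tables$cutpoint, Inf),
    events = de, nonevents = dn
  )
}

# aggregate interval counts back into the cumulative 2x2 table at the j-th
# cut-point: inverse of tables_to_intervals
intervals_to_table <- function(intervals, j) {
  e <- intervals$events
  n <- intervals$nonevents
  c(
    a = sum(e[seq_len(j)]), b = sum(n[seq_len(j)]),
    c = sum(e[-seq_len(j)]), d = sum(n[-seq_len(j)])
  )
}

#' Continuity correction for sparse 2x2 tables
#'
#' When a 2x2 table contains a zero cell, the log odds ratio is undefined;
#' following the treatment-arm continuity correction, each cell of a group
#' receives an increment equal to the reciprocal of the size of the
#' opposite group. Tables without zero cells are returned unchanged.
#'
#' @param a,b,c,d Cell counts: events/non-events at or below the cut-point
#'   (`a`, `b`) and above it (`c`, `d`).
#' @return A named numeric vector of (possibly fractional) pseudo-counts.
#' @export
#' @examples
#' continuity_correct(0, 10, 5, 5)
continuity_correct <- function(a, b, c, d) {
  a <- unname(a)
  b <- unname(b)
  c <- unname(c)
  d <- unname(d)
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  n_low <- a + b
  n_high <- c + d
  if (n_low == 0 || n_high == 0) {
    abort("a group with no subjects at all: continuity correction undefined")
  }
  if (all(c(a, b, c, d) > 0)) {
    return(c(a = a, b = b, c = c, d = d))
  }
  c(a = a + 1 / n_high, b = b + 1 / n_high, c = c + 1 / n_low, d = d + 1 / n_low)
}

# log OR and its large-sample variance from a (possibly corrected) table
log_or_cells <- function(cells) {
  cells <- unname(cells)
  c(
    lor = log(cells[1] * cells[4] / (cells[2] * cells[3])),
    var = sum(1 / cells)
  )
}

#' Bootstrap within-study correlations of log odds ratios across cut-points
#'
#' Resamples subjects with replacement from the participant-level data
#' reconstructed by [tables_to_intervals()], recomputes the log odds ratio
#' at every cut-point in each replicate (applying the continuity correction
#' of [continuity_correct()] whenever a replicate table has a zero cell),
#' and returns the empirical correlation and covariance matrices of the
#' log odds ratios across replicates. Replicates in which some cut-point
#' leaves one side of the split empty are redrawn, up to
#' `10 * n_boot` attempts in total.
#'
#' @param tables 2x2 tables as in [tables_to_intervals()].
#' @param n_boot Number of bootstrap replicates (at least 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return An object of class `boot_corr`: `corr` and `cov` matrices of the
#'   log odds ratios across cut-points, per-cut-point bootstrap `mean` and
#'   `se`, the plug-in estimates from the original table (`lor_obs`,
#'   `se_obs`), `n_boot`, `seed`, the number of continuity-corrected
#'   replicate tables (`n_corrected`) and of redrawn replicates
#'   (`n_redrawn`).
#' @export
boot_within_corr <- function(tables, n_boot = 1000, seed) {
  if (missing(seed)) abort("an explicit integer seed is required")
  if (n_boot < 100) abort("n_boot must be at least 100")
  intervals <- tables_to_intervals(tables)
  cutpoints <- intervals$upper[is.finite(intervals$upper)]
  T_ <- length(cutpoints)
  n_int <- nrow(intervals)
  N <- sum(intervals$events) + sum(intervals$nonevents)
  if (N < 10) abort("fewer than 10 subjects: bootstrap not meaningful")

  # expand to one row per subject: interval index and event status
  subj_int <- rep(intervals$interval, times = intervals$events + intervals$nonevents)
  subj_ev <- rep(
    rep(c(1L, 0L), n_int),
    times = as.vector(rbind(intervals$events, intervals$nonevents))
  )
  # bin id combining interval and event status for fast tabulation
  bin <- subj_int + n_int * subj_ev

  obs <- vapply(seq_len(T_), function(j) {
    log_or_cells(continuity_correct_v(intervals_to_table(intervals, j)))
  }, numeric(2))

  out <- matrix(NA_real_, n_boot, T_)
  n_corrected <- 0L
  n_redrawn <- 0L
  attempts <- 0L
  done <- 0L
  with_preserved_seed(seed, {
    while (done < n_boot) {
      attempts <- attempts + 1L
      if (attempts > 10L * n_boot) {
        abort("too many degenerate bootstrap replicates (a cut-point keeps emptying one group)")
      }
      idx <- sample.int(N, N, replace = TRUE)
      cnt <- tabulate(bin[idx], nbins = 2L * n_int)
      ne <- cnt[n_int + seq_len(n_int)]
      nn <- cnt[seq_len(n_int)]
      cum_e <- cumsum(ne)
      cum_n <- cumsum(nn)
      tot_e <- cum_e[n_int]
      tot_n <- cum_n[n_int]
      a <- cum_e[seq_len(T_)]
      b <- cum_n[seq_len(T_)]
      cc <- tot_e - a
      dd <- tot_n - b
      if (any(a + b == 0) || any(cc + dd == 0)) {
        n_redrawn <- n_redrawn + 1L
        next
      }
      lor <- numeric(T_)
      for (j in seq_len(T_)) {
        cells <- c(a[j], b[j], cc[j], dd[j])
        if (any(cells == 0)) {
          cells <- continuity_correct(cells[1], cells[2], cells[3], cells[4])
          n_corrected <- n_corrected + 1L
        }
        lor[j] <- log(cells[[1]] * cells[[4]] / (cells[[2]] * cells[[3]]))
      }
      done <- done + 1L
      out[done, ] <- lor
    }
  })

  lab <- format_num(cutpoints)
  covm <- cov(out)
  corrm <- cov2cor_safe(covm)
  dimnames(covm) <- dimnames(corrm) <- list(lab, lab)
  base::structure(
    list(
      corr = corrm, cov = covm,
      mean = setNames(colMeans(out), lab),
      se = setNames(apply(out, 2, sd), lab),
      lor_obs = setNames(obs[1, ], lab),
      se_obs = setNames(sqrt(obs[2, ]), lab),
      cutpoints = cutpoints, n_boot = n_boot, seed = seed,
      n_corrected = n_corrected, n_redrawn = n_redrawn,
      replicates = out
    ),
    class = "boot_corr"
  )
}

continuity_correct_v <- function(cells) {
  if (any(cells == 0)) {
    continuity_correct(cells["a"], cells["b"], cells["c"], cells["d"])
  } else {
    cells
  }
}

cov2cor_safe <- function(covm) {
  s <- sqrt(diag(covm))
  corrm <- covm / (s %o% s)
  corrm[!is.finite(corrm)] <- 0
  diag(corrm) <- 1
  corrm
}

# run code with a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Turn a bootstrap result into a correlation table for [meta_dataset()]
#'
#' @param x A `boot_corr` object.
#' @param study_id Study label for the output rows.
#' @param use `"cov"` (default) stores the bootstrap covariance of the log
#'   odds ratios; `"rho"` stores the bootstrap correlation instead (to be
#'   combined with the analytic standard errors).
#' @return A tibble with columns `study_id`, `level_a`, `level_b`, and
#'   `cov` or `rho`, with `provenance = "bootstrap"`.
#' @export
as_correlation_table <- function(x, study_id, use = c("cov", "rho")) {
  stopifnot(inherits(x, "boot_corr"))
  use <- match.arg(use)
  lab <- rownames(x$corr)
  pairs <- which(upper.tri(x$corr), arr.ind = TRUE)
  out <- tibble(
    study_id = as.character(study_id),
    level_a = lab[pairs[, 1]], level_b = lab[pairs[, 2]],
    rho = NA_real_, cov = NA_real_, provenance = "bootstrap"
  )
  if (use == "cov") {
    out$cov <- x$cov[pairs]
  } else {
    out$rho <- x$corr[pairs]
  }
  out
}

#' @export
print.boot_corr <- function(x, ...) {
  cat(
    "Bootstrap within-study correlations (", x$n_boot, " replicates, seed ",
    x$seed, ")\n",
    sep = ""
  )
  print(round(x$corr, 3))
  cat(
    "continuity-corrected tables:", x$n_corrected,
    "; redrawn replicates:", x$n_redrawn, "\n"
  )
  invisible(x)
}
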