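#' Maximum force response of a run
#'
#' Maximum of the (optionally moving-average smoothed) absolute pulled
#' force, with the time and pulled-group coordinate at which it occurs.
#' Window 1 (the default) means raw maxima.
#'
#' @param trace A `force_trace` (from [run_smd]) or data.frame with
#'   columns `time_ps`, `pulled_force` (optionally `membrane_force`,
#'   `pulled_com_x`).
#' @param smoothing_window Moving-average window in samples (odd, >= 1).
#' @param series Which series to maximize: `"pulled"` or `"membrane"`.
#' @return A one-row data.frame: `max_force`, `t_max_ps`, `com_x_at_max`.
#' @export
max_force <- function(trace, smoothing_window = 1L,
                      series = c("pulled", "membrane")) {
  series <- match.arg(series)
  if (nrow(trace) == 0) stop("empty force trace")
  stopifnot(smoothing_window >= 1)
  f <- abs(trace[[if (series == "pulled") "pulled_force" else
                  "membrane_force"]])
  w <- as.integer(smoothing_window)
  if (w > 1L) {
    f <- as.numeric(stats::filter(f, rep(1 / w, w), sides = 2))
  }
  i <- which.max(f)
  data.frame(max_force = f[i], t_max_ps = trace$time_ps[i],
             com_x_at_max = if ("pulled_com_x" %in% names(trace))
               trace$pulled_com_x[i] else NA_real_)
}

#' Aggregate per-run maxima into an experiment table
#'
#' Means, SDs and counts of per-replicate force maxima per
#' (peptide, velocity, mode) cell, in the shape of the published force
#' table: one row per peptide x velocity, columns `com` and `atom`.
#'
#' @param results Data.frame with columns `peptide`, `mode`
#'   (`"com"`/`"atom"`), `velocity`, `max_force`.
#' @return An object of class `experiment_table` (data.frame with columns
#'   `peptide, velocity, com, atom, com_sd, atom_sd, com_n, atom_n`).
#'   Cells with no runs are NA, never zero.
#' @export
aggregate_maxima <- function(results) {
  need <- c("peptide", "mode", "velocity", "max_force")
  stopifnot(all(need %in% names(results)))
  peps <- unique(results$peptide)
  vels <- sort(unique(results$velocity), decreasing = TRUE)
  rows <- list()
  for (p in peps) {
    for (v in vels) {
      row <- list(peptide = p, velocity = v)
      for (m in c("com", "atom")) {
        x <- results$max_force[results$peptide == p &
                                 results$velocity == v &
                                 results$mode == m]
        row[[m]] <- if (length(x)) mean(x) else NA_real_
        row[[paste0(m, "_sd")]] <- if (length(x) > 1) sd(x) else
          if (length(x) == 1) 0 else NA_real_
        row[[paste0(m, "_n")]] <- length(x)
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("experiment_table", "data.frame")
  out
}

#' Compare center-of-mass and terminal-atom pulling
#'
#' Per (peptide, velocity): mean maxima in both modes, their ratio, and
#' whether the center-of-mass response exceeds the terminal-atom one.
#'
#' @param table An `experiment_table`.
#' @return Data.frame `peptide, velocity, com, atom, ratio, com_gt_atom`;
#'   rows lacking either mode are dropped with a message.
#' @export
mode_comparison <- function(table) {
  tab <- as.data.frame(table)
  ok <- !is.na(tab$com) & !is.na(tab$atom)
  if (any(!ok)) {
    message(sum(!ok), " cells lack one of the two modes; skipped")
  }
  tab <- tab[ok, ]
  data.frame(peptide = tab$peptide, velocity = tab$velocity,
             com = tab$com, atom = tab$atom,
             ratio = tab$com / tab$atom,
             com_gt_atom = tab$com > tab$atom)
}

#' Monotonicity of force maxima in pulling velocity
#'
#' Checks, per peptide and mode, whether the mean force maximum is
#' non-decreasing in velocity; violations are listed, not raised.
#'
#' @param table An `experiment_table`.
#' @return Data.frame `peptide, mode, monotone, violations` (semicolon
#'   list of offending velocity pairs).
#' @export
velocity_trend <- function(table) {
  tab <- as.data.frame(table)
  rows <- list()
  for (p in unique(tab$peptide)) {
    for (m in c("com", "atom")) {
      sub <- tab[tab$peptide == p & !is.na(tab[[m]]), ]
      sub <- sub[order(sub$velocity), ]
      if (nrow(sub) < 2) next
      dif <- diff(sub[[m]])
      viol <- which(dif < 0)
      rows[[length(rows) + 1L]] <- data.frame(
        peptide = p, mode = m, monotone = length(viol) == 0,
        violations = if (length(viol)) {
          paste(sprintf("%g>%g", sub[[m]][viol], sub[[m]][viol + 1]),
                collapse = ";")
        } else {
          ""
        })
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group peptides by membrane reaction strength
#'
#' 1-D clustering of the mean force maxima of one (mode, velocity) column
#' into at most `k` ordered classes, either by k-means (deterministic
#' quantile initialization) or quantile thresholds. Class 1 is the
#' weakest reaction.
#'
#' @param table An `experiment_table`.
#' @param mode `"com"` or `"atom"`.
#' @param velocity Velocity column to use.
#' @param k Number of classes (default 4).
#' @param method `"kmeans"` or `"quantile"`.
#' @return A data.frame `peptide, value, class` (ordered class integers,
#'   1 = weakest) with the class centers/thresholds in attributes.
#' @export
group_by_reaction <- function(table, mode = c("atom", "com"),
                              velocity = 0.1, k = 4,
                              method = c("kmeans", "quantile")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  tab <- as.data.frame(table)
  sub <- tab[tab$velocity == velocity & !is.na(tab[[mode]]), ]
  x <- sub[[mode]]
  if (length(x) < max(4, k)) {
    stop("cell has only ", length(x), " peptides; need at least ",
         max(4, k))
  }
  ux <- unique(x)
  k_eff <- min(k, length(ux))  # identical values collapse classes
  if (k_eff == 1L) {
    out <- data.frame(peptide = sub$peptide, value = x, class = 1L)
    out <- out[order(out$value), ]
    rownames(out) <- NULL
    attr(out, "centers") <- mean(x)
    attr(out, "mode") <- mode
    attr(out, "velocity") <- velocity
    return(out)
  }
  if (k_eff >= length(ux)) {
    # one class per distinct value: assignment is the value rank
    cls <- match(x, sort(ux))
    thresholds <- sort(ux)
  } else if (method == "kmeans") {
    centers <- sort(unique(quantile(ux, probs = seq(0, 1,
                                                    length.out = k_eff))))
    km <- kmeans(x, centers = matrix(centers, ncol = 1), iter.max = 100)
    ord <- order(km$centers)
    cls <- match(km$cluster, ord)
    thresholds <- sort(km$centers)
  } else {
    qs <- quantile(x, probs = seq(0, 1, length.out = k_eff + 1))
    cls <- cut(x, breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
    thresholds <- qs
  }
  out <- data.frame(peptide = sub$peptide, value = x, class = cls)
  out <- out[order(out$value), ]
  rownames(out) <- NULL
  attr(out, "centers") <- as.numeric(thresholds)
  attr(out, "mode") <- mode
  attr(out, "velocity") <- velocity
  out
}

#' Published force-maxima table
#'
#' The packaged 15-row table of maximum peak forces averaged over 8
#' realizations per condition: 13 peptides plus the two lipid-pulling
#' controls, at wall velocities 0.1, 0.05 and 0.01 A/ps, pulled by the
#' center of mass (`com`) and by the terminal atom (`atom`). Cells the
#' study did not run (homo-repeats at 0.01 A/ps, lipid pulls beyond 0.1
#' com) are missing (NA), never imputed.
#'
#' @return An `experiment_table`.
#' @examples
#' t2 <- load_published_forces()
#' subset(t2, peptide == "P2" & velocity == 0.1)$com  # 7329
#' @export
load_published_forces <- function() {
  path <- pepsmd_extdata("published_force_maxima.tsv")
  expected_md5 <- "e9e7ddbb5d98d4a71b62da92859c1ef9"
  got <- tools::md5sum(path)[[1]]
  if (!identical(got, expected_md5)) {
    stop("packaged force table fails its integrity check (md5 ", got, ")")
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  class(tab) <- c("experiment_table", "data.frame")
  tab
}

#' @export
print.experiment_table <- function(x, ...) {
  cat("<experiment_table>", length(unique(x$peptide)), "peptides x",
      length(unique(x$velocity)), "velocities\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a force trace
#'
#' Pulled (red) and membrane (black) spring forces against time, the
#' usual way a pulling force response is displayed.
#'
#' @param x A `force_trace`.
#' @param ... Passed to [graphics::plot].
#' @export
plot.force_trace <- function(x, ...) {
  graphics::plot(x$time_ps, x$pulled_force, type = "l", col = "red",
                 xlab = "time (ps)", ylab = "force (kJ/mol/A)",
                 ylim = range(c(x$pulled_force, x$membrane_force)), ...)
  graphics::lines(x$time_ps, x$membrane_force, col = "black")
  graphics::legend("topleft", c("pulled", "membrane"),
                   col = c("red", "black"), lty = 1, bty = "n")
  invisible(x)
}
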