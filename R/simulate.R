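# Synthetic replicate-level data with the statistical structure the analysis
# assumes: group-structured measurements drawn around published means +/- SD.

#' Simulation configuration
#'
#' Describes the stated world of a simulated dataset: per-(analyte, form,
#' group) means and SDs (typically the published group-mean table), a
#' replicate count, a seed, and optional extras (a discriminating set for
#' variable-recovery experiments, an e-nose sensor profile).
#'
#' @param means an [analyte_table()] of group means whose `sd` column holds
#'   the matching standard deviations (every mean must have one).
#' @param n_replicates replicates per group, at least 2 so within-group
#'   variance is estimable (default 3, standard triplicate practice in food
#'   chemistry).
#' @param seed integer seed; identical configurations give identical tables.
#' @param noise_model only `"gaussian_truncated_at_zero"` is implemented:
#'   draws are Normal(mean, SD) conditioned on being non-negative, matching
#'   mean +/- SD reporting while never emitting a negative amount.
#' @param renormalize for `relative_percent` tables, rescale each simulated
#'   replicate to sum to 100% after noise injection (mirrors the
#'   semi-quantification normalization); ignored for concentration tables.
#' @param enose_profile optional data.frame `sensor`, `group`, `mean`, `sd`
#'   for [simulate_enose()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(means, n_replicates = 3, seed = 1,
                              noise_model = "gaussian_truncated_at_zero",
                              renormalize = TRUE, enose_profile = NULL) {
  stopifnot(inherits(means, "analyte_table"))
  noise_model <- match.arg(noise_model, "gaussian_truncated_at_zero")
  if (!is.numeric(n_replicates) || n_replicates < 2)
    stop("config error: n_replicates must be at least 2", call. = FALSE)
  if (any(is.na(means$sd)))
    stop("config error: every (analyte, form, group) mean needs an SD",
         call. = FALSE)
  structure(list(means = means, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), noise_model = noise_model,
                 renormalize = isTRUE(renormalize),
                 enose_profile = enose_profile),
            class = "simulation_config")
}

# Normal(mean, sd) truncated at zero via inverse-CDF sampling; sd = 0
# degenerates to the mean.
.rtruncnorm0 <- function(n, mean, sd) {
  x <- rep(mean, length.out = n)
  pos <- sd > 0
  if (any(pos)) {
    lo <- stats::pnorm(0, mean[pos], sd[pos])
    u <- stats::runif(sum(pos), lo, 1)
    x[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  pmax(x, 0)
}

#' Simulate replicate-level measurements
#'
#' Draws `n_replicates` values per (analyte, form, group) from
#' Normal(mean, SD) truncated at zero. Deterministic given the seed.
#'
#' @param config a [simulation_config()].
#' @return an [analyte_table()] with a `replicate` column.
#' @export
simulate_replicates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  m <- as.data.frame(config$means)
  n <- config$n_replicates
  set.seed(config$seed)
  out <- do.call(rbind, lapply(seq_len(n), function(r) {
    d <- m[, c("analyte_id", "form", "sample_group")]
    d$replicate <- r
    d$value <- NA_real_
    d
  }))
  # draw in a fixed (row-major by replicate) order for reproducibility
  out$value <- .rtruncnorm0(nrow(out), rep(m$value, n), rep(m$sd, n))
  tab <- analyte_table(out, value_kind(config$means))
  if (value_kind(tab) == "relative_percent" && config$renormalize)
    tab <- normalize_to_relative_content(tab)
  tab
}

#' Default electronic-nose sensor profile
#'
#' A ten-sensor array over the five cooking-time groups. Sensors S2, S3 and
#' S6 sit well above the rest in every group (the qualitative pattern of the
#' study's sensor array), and the overall response peaks in group D
#' (120 min). Units are arbitrary response units.
#'
#' @param groups group labels (default A--E).
#' @param sd per-observation noise SD (default 0.05).
#' @return data.frame `sensor`, `group`, `mean`, `sd`.
#' @export
default_enose_profile <- function(groups = c("A", "B", "C", "D", "E"),
                                  sd = 0.05) {
  base <- c(S1 = 1.0, S2 = 2.8, S3 = 3.2, S4 = 1.2, S5 = 0.9,
            S6 = 2.5, S7 = 1.1, S8 = 1.3, S9 = 0.8, S10 = 1.0)
  lift <- c(1.00, 1.05, 1.10, 1.20, 1.15)[seq_along(groups)]
  out <- expand.grid(sensor = names(base), group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean <- base[out$sensor] * lift[match(out$group, groups)]
  out$sd <- sd
  out
}

#' Simulate an electronic-nose response table
#'
#' Sensors play the role of analytes; five parallel repeats are drawn per
#' group (the standard e-nose protocol). Group structure in the profile is
#' recoverable by PCA on the resulting table.
#'
#' @param config a [simulation_config()] with a non-`NULL` `enose_profile`.
#' @param n_repeats parallel measurements per group (default 5).
#' @return an [analyte_table()] (`relative_percent` kind, sensors as
#'   analytes).
#' @export
simulate_enose <- function(config, n_repeats = 5) {
  stopifnot(inherits(config, "simulation_config"))
  pr <- config$enose_profile
  if (is.null(pr))
    stop("config error: enose_profile missing", call. = FALSE)
  set.seed(config$seed + 1L)
  out <- do.call(rbind, lapply(seq_len(n_repeats), function(r) {
    d <- data.frame(analyte_id = pr$sensor, sample_group = pr$group,
                    replicate = r, stringsAsFactors = FALSE)
    d
  }))
  out$value <- .rtruncnorm0(nrow(out), rep(pr$mean, n_repeats),
                            rep(pr$sd, n_repeats))
  analyte_table(out, "relative_percent")
}

#' Inject between-group discrimination into a group-mean table
#'
#' Shifts the group means of the listed analytes by up to `shift` pooled SDs
#' along a monotone pattern across the ordered groups (first group lowest,
#' last highest), leaving all other analytes untouched. Each listed analyte
#' is assigned one of a fixed family of monotone ramp shapes (linear,
#' saturating, accelerating; cycled in listing order), so a multi-analyte
#' discriminating set spans several independent between-group directions
#' rather than one shared gradient -- the situation a multi-class
#' discriminant analysis can actually resolve. Used as ground truth for VIP
#' recovery experiments: a large `shift` makes exactly these analytes
#' discriminating.
#'
#' @param table an [analyte_table()] of group means with SDs.
#' @param ids analyte names to make discriminating (form suffixes allowed).
#' @param shift shift size in multiples of the analyte's pooled SD.
#' @return the modified [analyte_table()] (means truncated at zero).
#' @export
inject_discrimination <- function(table, ids, shift) {
  stopifnot(inherits(table, "analyte_table"))
  if (shift == 0) return(table)
  out <- as.data.frame(table)
  groups <- sort(unique(out$sample_group))
  g <- length(groups)
  u <- if (g > 1) (seq_len(g) - 1) / (g - 1) else 0.5
  shapes <- c(0.25, 0.5, 1, 2, 4)        # monotone u^p ramps, rescaled to [-1, 1]
  for (j in seq_along(ids)) {
    id <- ids[j]
    sf <- split_form(id)
    hit <- canonical_id(out$analyte_id) == canonical_id(sf$analyte_id) &
      (sf$form == "none" | out$form == sf$form)
    if (!any(hit))
      stop("inject_discrimination: unknown analyte '", id, "'", call. = FALSE)
    ramp <- 2 * u^shapes[(j - 1) %% length(shapes) + 1] - 1
    names(ramp) <- groups
    sd_pool <- sqrt(mean(out$sd[hit]^2))
    out$value[hit] <- pmax(0, out$value[hit] +
                             shift * sd_pool * ramp[out$sample_group[hit]])
  }
  analyte_table(out, value_kind(table))
}
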