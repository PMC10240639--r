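#' Extract per-trial stance metrics
#'
#' Peak PFJ contact force over the stance interval (earliest sample wins
#' exact ties), with knee flexion angle and quadriceps force read at the
#' same sample, peak timing on the 0--100% stance axis, and the trial's
#' approach velocity. Samples flagged infeasible by the static optimizer
#' are excluded from peak extraction.
#'
#' @param pfj a \code{pfj_force_series}.
#' @param kin a \code{joint_kinematics} on the same clock.
#' @param stance_idx integer sample indices spanning stance.
#' @param velocity approach velocity (m/s) for the trial.
#' @param feasible optional logical per-sample feasibility flags.
#' @param participant_id,limb,trial optional labels carried through.
#' @return one-row data.frame of class \code{stance_metrics}.
#' @export
extract_metrics <- function(pfj, kin, stance_idx, velocity,
                            feasible = NULL, participant_id = NA_character_,
                            limb = NA_character_, trial = NA_integer_) {
  stopifnot(inherits(pfj, "pfj_force_series"))
  s <- pfj$series
  if (length(stance_idx) == 0) stop("input error: stance interval is empty")
  if (!is.na(limb) && !limb %in% c("ACLR", "contralateral", "control"))
    stop("input error: limb must be ACLR, contralateral or control")
  ok <- stance_idx
  if (!is.null(feasible)) ok <- stance_idx[feasible[stance_idx]]
  if (length(ok) == 0)
    stop("metrics-unavailable error: all stance samples flagged infeasible")
  peak_at <- ok[which.max(s$f_pfj[ok])]   # which.max returns the earliest tie
  span <- range(kin$time[stance_idx])
  out <- data.frame(
    participant_id = participant_id, limb = limb, trial = trial,
    peak_pfj = s$f_pfj[peak_at],
    angle_at_peak = kin$angles[peak_at, "knee"],
    quad_at_peak = s$f_q[peak_at],
    approach_velocity = as.numeric(velocity),
    peak_time_pct = 100 * (kin$time[peak_at] - span[1]) / diff(span),
    n_flagged = length(stance_idx) - length(ok),
    clamped_any = any(s$clamped[ok]),
    stringsAsFactors = FALSE)
  class(out) <- c("stance_metrics", class(out))
  out
}

limb_levels <- c("ACLR", "contralateral", "control")

# accept either the per-trial extract_metrics column names or the CSV
# metrics-table schema; returns the CSV schema
normalize_metrics_table <- function(metrics) {
  map <- c(peak_pfj = "peak_pfj_bw", angle_at_peak = "knee_angle_deg",
           quad_at_peak = "quad_force_bw",
           approach_velocity = "approach_velocity_ms")
  for (from in names(map)) {
    to <- map[[from]]
    if (!to %in% names(metrics) && from %in% names(metrics))
      names(metrics)[names(metrics) == from] <- to
  }
  metrics
}

metric_column <- function(outcome) {
  switch(outcome,
         peak_pfj = "peak_pfj_bw", angle_at_peak = "knee_angle_deg",
         quad_at_peak = "quad_force_bw",
         stop("input error: unknown outcome '", outcome, "'"))
}

#' Fit the velocity-adjusted mixed model comparing limbs
#'
#' Fits \code{outcome ~ limb + approach_velocity + (1 | participant)} by
#' REML on trial-level rows, then computes velocity-adjusted marginal
#' means per limb at the pooled mean approach velocity, their 95% CIs, and
#' all three pairwise limb differences with Tukey-adjusted p-values.
#' Degrees of freedom for CIs and Tukey tests use a between-participant
#' containment approximation (participants minus limb levels); Satterthwaite
#' machinery is deliberately not reimplemented here. A singular fit (zero
#' between-participant variance) returns a result with a singularity
#' warning rather than aborting.
#'
#' @param metrics data.frame in the metrics-table schema
#'   (\code{participant_id}, \code{limb}, \code{trial},
#'   \code{peak_pfj_bw}, \code{knee_angle_deg}, \code{quad_force_bw},
#'   \code{approach_velocity_ms}).
#' @param outcome one of \code{"peak_pfj"}, \code{"angle_at_peak"},
#'   \code{"quad_at_peak"}.
#' @param conf_level confidence level for intervals.
#' @return object of class \code{limb_comparison}: fixed effects with SEs,
#'   marginal means with CIs, Tukey pairwise contrasts, variance
#'   components and diagnostics.
#' @export
fit_limb_model <- function(metrics, outcome = "peak_pfj",
                           conf_level = 0.95) {
  metrics <- normalize_metrics_table(metrics)
  col <- metric_column(outcome)
  need <- c("participant_id", "limb", "approach_velocity_ms", col)
  if (!all(need %in% names(metrics)))
    stop("input error: metrics table lacks column(s): ",
         paste(setdiff(need, names(metrics)), collapse = ", "))
  d <- data.frame(
    y = metrics[[col]],
    limb = factor(metrics$limb, levels = limb_levels),
    v = metrics$approach_velocity_ms,
    participant = factor(metrics$participant_id))
  if (anyNA(d$limb)) stop("input error: limb labels outside the closed set")
  counts <- table(unique(d[c("participant", "limb")])$limb)
  if (any(counts < 2))
    stop("rank-deficient design: fewer than 2 participants in group(s) ",
         paste(names(counts)[counts < 2], collapse = ", "))
  notes <- character()
  fit <- withCallingHandlers(
    lme4::lmer(y ~ limb + v + (1 | participant), data = d, REML = TRUE),
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, conditionMessage(m))
      invokeRestart("muffleMessage")
    })
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) notes <- c(notes, "singular fit: between-participant variance estimated at zero")
  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  vbar <- mean(d$v)

  # marginal means: L beta evaluated at the pooled mean velocity
  L <- rbind(
    ACLR          = c(1, 0, 0, vbar),
    contralateral = c(1, 1, 0, vbar),
    control       = c(1, 0, 1, vbar))
  mm <- as.numeric(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  df <- max(nlevels(d$participant) - length(limb_levels), 2)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  marginal <- data.frame(limb = limb_levels, emmean = mm, se = se, df = df,
                         lower = mm - tcrit * se, upper = mm + tcrit * se)

  pairs <- utils::combn(limb_levels, 2)
  k <- nrow(L)
  qcrit <- stats::qtukey(conf_level, k, df) / sqrt(2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    Lc <- L[a, ] - L[b, ]
    est <- as.numeric(Lc %*% beta)
    sec <- sqrt(as.numeric(t(Lc) %*% V %*% Lc))
    p <- stats::ptukey(abs(est) / sec * sqrt(2), k, df, lower.tail = FALSE)
    data.frame(contrast = paste(a, "-", b), estimate = est, se = sec,
               df = df, lower = est - qcrit * sec, upper = est + qcrit * sec,
               p_adj = p, stringsAsFactors = FALSE)
  }))

  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    outcome = outcome,
    fixed_effects = data.frame(term = names(beta), estimate = beta,
                               se = sqrt(diag(V)), row.names = NULL),
    marginal_means = marginal,
    contrasts = contrasts,
    variance_components = data.frame(
      component = c("participant_intercept_sd", "residual_sd"),
      value = c(vc$sdcor[vc$grp == "participant"],
                vc$sdcor[vc$grp == "Residual"])),
    pooled_velocity = vbar, df = df, conf_level = conf_level,
    singular = singular, notes = notes, n_obs = nrow(d),
    n_participants = nlevels(d$participant)),
    class = "limb_comparison")
}

#' @export
print.limb_comparison <- function(x, ...) {
  cat("Limb comparison for", x$outcome,
      sprintf("(velocity-adjusted at %.3f m/s%s)\n", x$pooled_velocity,
              if (x$singular) "; SINGULAR fit" else ""))
  print(x$marginal_means, row.names = FALSE, digits = 4)
  cat("Tukey pairwise contrasts:\n")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the limb comparison for all three outcomes
#'
#' @param metrics metrics table (see \code{\link{fit_limb_model}}).
#' @param outcomes outcome names to fit.
#' @return object of class \code{limb_report}: one
#'   \code{limb_comparison} per outcome plus a 3 limbs x 3 outcomes
#'   marginal-mean summary table.
#' @export
compare_all <- function(metrics, outcomes = c("peak_pfj", "angle_at_peak",
                                              "quad_at_peak")) {
  if (is.null(metrics) || nrow(metrics) == 0)
    stop("input error: empty metrics table")
  results <- lapply(outcomes, function(o) fit_limb_model(metrics, o))
  names(results) <- outcomes
  summary_tab <- do.call(rbind, lapply(outcomes, function(o) {
    mm <- results[[o]]$marginal_means
    data.frame(outcome = o, limb = mm$limb,
               emmean = mm$emmean, lower = mm$lower, upper = mm$upper)
  }))
  structure(list(results = results, summary = summary_tab),
            class = "limb_report")
}

#' @export
print.limb_report <- function(x, ...) {
  tab <- x$summary
  tab$cell <- sprintf("%.1f (%.1f-%.1f)", tab$emmean, tab$lower, tab$upper)
  wide <- stats::reshape(tab[, c("outcome", "limb", "cell")],
                         idvar = "limb", timevar = "outcome",
                         direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  cat("Marginal means (95% CI), accounting for approach velocity\n")
  print(wide, row.names = FALSE)
  invisible(x)
}
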