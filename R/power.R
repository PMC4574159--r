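#' Expected case/control allele frequencies from a penetrance model
#'
#' Derives genotype penetrances from disease prevalence, risk-allele frequency
#' and genotype relative risk under a named inheritance model (`dominant`:
#' `f1 = f2 = GRR·f0`; `recessive`: `f1 = f0`, `f2 = GRR·f0`;
#' `multiplicative`: `f1 = GRR·f0`, `f2 = GRR²·f0`; `additive`:
#' `f1 = GRR·f0`, `f2 = (2·GRR − 1)·f0`), solving `K = Σ g_i f_i` for the
#' baseline penetrance, then computes the expected risk-allele frequencies in
#' cases and in controls (non-cases).
#'
#' @param prevalence Disease prevalence `K` in (0, 1).
#' @param daf Risk (disease) allele frequency in the population, in (0, 1).
#' @param grr Genotype relative risk, > 0.
#' @param model Inheritance model.
#' @return A list with `penetrances` (length 3), `p_case`, `p_ctrl`,
#'   `geno_case`, `geno_ctrl`.
#' @export
penetrance_model <- function(prevalence, daf, grr,
                             model = c("dominant", "recessive",
                                       "multiplicative", "additive")) {
  model <- match.arg(model)
  if (prevalence <= 0 || prevalence >= 1) abort("prevalence must be in (0, 1).")
  if (daf <= 0 || daf >= 1) abort("daf must be in (0, 1).")
  if (grr <= 0) abort("grr must be > 0.")
  g <- c((1 - daf)^2, 2 * daf * (1 - daf), daf^2)
  w <- switch(model,
              dominant = c(1, grr, grr),
              recessive = c(1, 1, grr),
              multiplicative = c(1, grr, grr^2),
              additive = c(1, grr, 2 * grr - 1))
  f0 <- prevalence / sum(g * w)
  f <- f0 * w
  if (any(f < 0 | f > 1)) {
    abort("Prevalence, allele frequency and GRR are jointly infeasible: ",
          "a penetrance falls outside [0, 1].")
  }
  geno_case <- g * f / prevalence
  geno_ctrl <- g * (1 - f) / (1 - prevalence)
  list(penetrances = f,
       p_case = geno_case[2] / 2 + geno_case[3],
       p_ctrl = geno_ctrl[2] / 2 + geno_ctrl[3],
       geno_case = geno_case, geno_ctrl = geno_ctrl)
}

#' Analytic power of a case-control allele-frequency test
#'
#' Computes the power of the allele-based comparison of cases and controls at
#' significance level `alpha`, in the style of standard genetic power
#' calculators: penetrances are derived from (prevalence, allele frequency,
#' GRR, model), expected case/control allele frequencies follow, and power is
#' the normal-approximation tail probability of the Wald z statistic (allele
#' counts `2·n`, variance estimated under the alternative — the statistic of
#' [allele_wald_test()]). `sided = 1` (default) evaluates the test in the
#' direction of the modelled effect; `sided = 2` adds the opposite tail at
#' `alpha/2` per side.
#'
#' @inheritParams penetrance_model
#' @param alpha Significance level.
#' @param n_cases,n_controls Numbers of case and control subjects.
#' @param sided 1 or 2.
#' @return A `power_calc` object; `$power` holds the power in `[0, 1]`.
#'   `tidy()` returns a one-row tibble.
#' @export
#' @examples
#' cats_power(prevalence = 0.01, daf = 0.08, grr = 4.35, model = "dominant",
#'            alpha = 1e-7, n_cases = 176, n_controls = 358)
cats_power <- function(prevalence, daf, grr,
                       model = c("dominant", "recessive", "multiplicative",
                                 "additive"),
                       alpha = 5e-8, n_cases, n_controls, sided = 1) {
  model <- match.arg(model)
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1).")
  if (!sided %in% c(1, 2)) abort("sided must be 1 or 2.")
  pm <- penetrance_model(prevalence, daf, grr, model)
  n1 <- 2 * n_cases; n2 <- 2 * n_controls
  diff <- abs(pm$p_case - pm$p_ctrl)
  se <- sqrt(pm$p_case * (1 - pm$p_case) / n1 +
               pm$p_ctrl * (1 - pm$p_ctrl) / n2)
  mu <- if (se == 0) 0 else diff / se
  power <- if (sided == 1) {
    pnorm(mu - qnorm(1 - alpha))
  } else {
    zc <- qnorm(1 - alpha / 2)
    pnorm(mu - zc) + pnorm(-mu - zc)
  }
  structure(list(power = power, ncp = mu^2,
                 p_case = pm$p_case, p_ctrl = pm$p_ctrl,
                 penetrances = pm$penetrances,
                 prevalence = prevalence, daf = daf, grr = grr, model = model,
                 alpha = alpha, sided = sided,
                 n_cases = n_cases, n_controls = n_controls),
            class = "power_calc")
}

#' @export
print.power_calc <- function(x, ...) {
  cat(sprintf(
    "Case-control allele-test power: %.1f%%\n  model=%s GRR=%.3g daf=%.3g prevalence=%.3g alpha=%.3g (%d-sided)\n  %d cases / %d controls; expected allele freq %.4f (cases) vs %.4f (controls)\n",
    100 * x$power, x$model, x$grr, x$daf, x$prevalence, x$alpha, x$sided,
    x$n_cases, x$n_controls, x$p_case, x$p_ctrl))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.power_calc <- function(x, ...) {
  tibble(power = x$power, model = x$model, grr = x$grr, daf = x$daf,
         prevalence = x$prevalence, alpha = x$alpha, sided = x$sided,
         n_cases = x$n_cases, n_controls = x$n_controls,
         p_case = x$p_case, p_ctrl = x$p_ctrl)
}

#' @exportS3Method generics::glance
glance.power_calc <- function(x, ...) tidy(x)

#' Monte-Carlo power by cohort simulation
#'
#' Validates [cats_power()] by simulation: the same penetrance model fixes the
#' expected case/control allele frequencies, cohorts are drawn with
#' [simulate_cohort()] (allelic tilt reproducing those frequencies exactly),
#' and each replicate is tested with the identical statistic the analytic
#' formula models ([allele_wald_test()], one- or two-sided to match).
#'
#' @inheritParams cats_power
#' @param n_sims Number of simulated cohorts.
#' @param seed Integer seed.
#' @return A tibble with `power_mc`, `mc_se`, `n_sims` and the analytic
#'   `power` for reference.
#' @export
power_mc <- function(prevalence, daf, grr, model = "dominant",
                     alpha = 5e-8, n_cases, n_controls,
                     sided = 1, n_sims = 1000, seed = 1L) {
  analytic <- cats_power(prevalence, daf, grr, model, alpha,
                         n_cases, n_controls, sided)
  p1 <- analytic$p_case; p2 <- analytic$p_ctrl
  or_allelic <- (p1 / (1 - p1)) / (p2 / (1 - p2))
  direction <- if (p1 >= p2) "greater" else "less"
  hits <- logical(n_sims)
  set.seed(seed)
  seeds <- sample.int(2^30, n_sims)
  for (k in seq_len(n_sims)) {
    cohort <- simulate_cohort(cohort_sim_config(
      n_cases = n_cases, n_controls = n_controls,
      p0 = p2, or = or_allelic, model = "allelic", seed = seeds[k]))
    dos <- cohort[[3]]
    alt_case <- sum(dos[cohort$status == "case"])
    alt_ctrl <- sum(dos[cohort$status == "control"])
    wt <- allele_wald_test(alt_case, 2 * n_cases - alt_case,
                           alt_ctrl, 2 * n_controls - alt_ctrl,
                           alternative = if (sided == 1) direction
                                         else "two.sided")
    hits[k] <- wt$p < alpha
  }
  pw <- mean(hits)
  tibble(power_mc = pw, mc_se = sqrt(pw * (1 - pw) / n_sims),
         n_sims = n_sims, power_analytic = analytic$power)
}
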