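#' Specify a synthetic clinical cohort
#'
#' Describes the world the cohort generator draws from: a case--control sample
#' of pregnancies with 14 collected variables, class-conditional shifts for
#' the risk-bearing features (lower PlGF, higher blood pressure and BMI in
#' cases), two strongly dependent feature pairs (pre-pregnancy vs. current
#' weight, which also depends on gestational age, and diastolic vs. systolic
#' pressure), a 5-level ethnicity factor, two PlGF measurement platforms
#' related by a monotone affine transfer, and missing entries injected
#' completely at random.
#'
#' Defaults mirror the study design the pipeline targets: 145 cases vs. 559
#' controls (a strongly imbalanced mono-platform set), about 1/4 of maskable
#' cells missing, and gestational ages between 11 weeks and 33 weeks + 6 days.
#'
#' @param n_cases,n_controls class sizes (both >= 1).
#' @param missing_rate fraction in `[0, 1)` of maskable cells set missing.
#' @param platform_mix fraction of records measured on SiMoA (rest Elecsys).
#' @param gestational_day_range integer day interval, default 77--237
#'   (11w+0d to 33w+6d).
#' @param effect_sizes named list of case-minus-control mean shifts in feature
#'   units for `plgf` (pg/mL), `diastolic_pressure` (mmHg),
#'   `pre_pregnancy_weight` (kg) and `age` (years).
#' @param pair_noise_sd residual SD for the two dependent pairs (kg / mmHg).
#' @param transfer_params list with `slope`, `intercept`, `noise_sd` of the
#'   SiMoA -> Elecsys PlGF transfer.
#' @param seed integer seed; every draw is reproducible under it.
#' @return an object of class `perisk_cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_cases = 20, n_controls = 60, seed = 1)
#' cohort <- generate_cohort(spec)
#' table(cohort$label)
cohort_spec <- function(n_cases = 145L, n_controls = 559L,
                        missing_rate = 0.25, platform_mix = 0.5,
                        gestational_day_range = c(77L, 237L),
                        effect_sizes = list(plgf = -150,
                                            diastolic_pressure = 12,
                                            pre_pregnancy_weight = 6,
                                            age = 1),
                        pair_noise_sd = 4,
                        transfer_params = list(slope = 1.3, intercept = 10,
                                               noise_sd = 5),
                        seed = 0L) {
  if (length(n_cases) != 1L || n_cases < 1L) stopf("n_cases must be >= 1")
  if (length(n_controls) != 1L || n_controls < 1L) stopf("n_controls must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stopf("missing_rate must lie in [0, 1)")
  if (platform_mix < 0 || platform_mix > 1) stopf("platform_mix must lie in [0, 1]")
  if (pair_noise_sd < 0) stopf("pair_noise_sd must be >= 0")
  if (length(gestational_day_range) != 2L ||
      gestational_day_range[1] > gestational_day_range[2])
    stopf("gestational_day_range must be an ordered day interval")
  defaults <- list(plgf = -150, diastolic_pressure = 12,
                   pre_pregnancy_weight = 6, age = 1)
  effect_sizes <- utils::modifyList(defaults, as.list(effect_sizes))
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 missing_rate = missing_rate, platform_mix = platform_mix,
                 gestational_day_range = as.integer(gestational_day_range),
                 effect_sizes = effect_sizes, pair_noise_sd = pair_noise_sd,
                 transfer_params = transfer_params, seed = as.integer(seed)),
            class = "perisk_cohort_spec")
}

ETHNICITY_LEVELS <- c("Han", "Uygur", "Kazak", "Hui", "other")
PLATFORM_LEVELS <- c("SiMoA", "Elecsys")

# weight gain per gestational day (kg/day) and systolic~diastolic line used by
# the generator; tests recover these as ground truth
WEIGHT_GAIN_PER_DAY <- 0.045
SBP_SLOPE <- 1.1
SBP_INTERCEPT <- 38

rnorm_trunc <- function(n, mean, sd, lo, hi) pmin(pmax(rnorm(n, mean, sd), lo), hi)

#' Generate a synthetic cohort table
#'
#' Draws `n_cases + n_controls` clinical records. Continuous features come
#' from truncated normals within physiologic ranges; history codes are
#' Bernoulli/binomial with class-dependent rates; ethnicity is multinomial.
#' Current weight is pre-pregnancy weight plus a gestational-day-dependent
#' gain plus noise; systolic pressure is an affine function of diastolic
#' pressure plus noise, so both dependent-pair relations are known exactly.
#' PlGF is generated on the SiMoA-native scale; records tagged Elecsys report
#' the value pushed through the platform transfer (the SiMoA-scale truth is
#' kept in the `"plgf_simoa"` attribute for calibration oracles).
#'
#' @param spec a [cohort_spec()].
#' @return a `data.frame` of class `perisk_cohort`, one row per pregnancy,
#'   with columns age, ethnicity, height, pre_pregnancy_weight,
#'   current_weight, pregnancy_history, fertility_history, pe_history,
#'   family_pe_history, hypertension_history, gest_weeks, gest_days,
#'   diastolic_pressure, systolic_pressure, plgf, platform, label.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "perisk_cohort_spec")) stopf("spec must come from cohort_spec()")
  set.seed(derive_seed(spec$seed, "generate_cohort"))
  n <- spec$n_cases + spec$n_controls
  label <- factor(rep(c("case", "control"), c(spec$n_cases, spec$n_controls)),
                  levels = c("control", "case"))
  case <- label == "case"
  es <- spec$effect_sizes

  gd <- sample(seq(spec$gestational_day_range[1], spec$gestational_day_range[2]),
               n, replace = TRUE)
  age <- round(rnorm_trunc(n, 28 + es$age * case, 5, 18, 45), 1)
  ethnicity <- factor(sample(ETHNICITY_LEVELS, n, replace = TRUE,
                             prob = c(0.50, 0.28, 0.10, 0.07, 0.05)),
                      levels = ETHNICITY_LEVELS)
  height <- round(rnorm_trunc(n, 1.60, 0.06, 1.40, 1.90), 2)
  pre_w <- round(rnorm_trunc(n, 58 + es$pre_pregnancy_weight * case, 9, 40, 110), 1)
  cur_w <- pre_w + WEIGHT_GAIN_PER_DAY * gd + rnorm(n, 0, spec$pair_noise_sd)
  cur_w <- round(pmax(cur_w, pre_w), 1)

  dbp <- rnorm_trunc(n, 72 + es$diastolic_pressure * case, 8, 45, 120)
  sbp <- SBP_SLOPE * dbp + SBP_INTERCEPT + rnorm(n, 0, spec$pair_noise_sd)
  sbp <- pmax(sbp, dbp + 2)
  if (spec$pair_noise_sd > 0) { dbp <- round(dbp); sbp <- round(sbp) }

  plgf_simoa <- rnorm_trunc(n, 320 + es$plgf * case, 120, 10, 2000)
  platform <- factor(ifelse(runif(n) < spec$platform_mix, "SiMoA", "Elecsys"),
                     levels = PLATFORM_LEVELS)
  tp <- spec$transfer_params
  plgf <- ifelse(platform == "SiMoA", plgf_simoa,
                 pmax(tp$slope * plgf_simoa + tp$intercept +
                        rnorm(n, 0, tp$noise_sd), 1))
  plgf <- round(plgf, 1)

  out <- data.frame(
    age = age, ethnicity = ethnicity, height = height,
    pre_pregnancy_weight = pre_w, current_weight = cur_w,
    pregnancy_history = rbinom(n, 3, 0.40),
    fertility_history = rbinom(n, 2, 0.35),
    pe_history = rbinom(n, 1, ifelse(case, 0.15, 0.02)),
    family_pe_history = rbinom(n, 1, ifelse(case, 0.15, 0.05)),
    hypertension_history = rbinom(n, 1, ifelse(case, 0.20, 0.03)),
    gest_weeks = gd %/% 7L, gest_days = gd %% 7L,
    diastolic_pressure = dbp, systolic_pressure = sbp,
    plgf = plgf, platform = platform, label = label,
    stringsAsFactors = FALSE)
  out <- inject_missingness(out, spec$missing_rate,
                            derive_seed(spec$seed, "inject_missingness"))
  attr(out, "plgf_simoa") <- round(plgf_simoa, 1)
  attr(out, "spec") <- spec
  class(out) <- c("perisk_cohort", "data.frame")
  out
}

# columns that may never be masked: identity of the record's fold role
UNMASKABLE <- c("gest_weeks", "gest_days", "platform", "label")

#' Inject missingness completely at random
#'
#' Masks each maskable cell independently with probability `rate`. The label,
#' platform and gestational-age columns are never masked.
#'
#' @param table a cohort `data.frame`.
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed; identical seeds give identical masks.
#' @return the table with `NA`s injected.
#' @export
inject_missingness <- function(table, rate, seed = 0L) {
  if (rate < 0 || rate >= 1) stopf("rate must lie in [0, 1)")
  if (rate == 0) return(table)
  set.seed(as.integer(seed))
  maskable <- setdiff(names(table), UNMASKABLE)
  for (col in maskable) {
    mask <- runif(nrow(table)) < rate
    table[[col]][mask] <- NA
  }
  table
}

#' Generate a paired PlGF calibration set
#'
#' Emulates a small calibration study in which the same samples are assayed on
#' both platforms: SiMoA-scale values `s_i` are drawn from a physiologic PlGF
#' range and Elecsys-scale values follow
#' `e_i = slope * s_i + intercept + noise`.
#'
#' @param n number of paired samples (>= 3 so a 3-fold split is possible);
#'   default 24.
#' @param transfer_params list with `slope`, `intercept`, `noise_sd`.
#' @param seed integer seed.
#' @return a `data.frame` of class `perisk_calpairs` with columns `simoa` and
#'   `elecsys`, no missing values, all positive.
#' @export
generate_calibration_set <- function(n = 24L,
                                     transfer_params = list(slope = 1.3,
                                                            intercept = 10,
                                                            noise_sd = 5),
                                     seed = 0L) {
  if (n < 3L) stopf("need at least 3 pairs for a 3-fold split, got %d", n)
  set.seed(derive_seed(seed, "calibration_set"))
  tp <- transfer_params
  s <- rnorm_trunc(n, 300, 150, 20, 1000)
  e <- pmax(tp$slope * s + tp$intercept + rnorm(n, 0, tp$noise_sd), 1)
  structure(data.frame(simoa = s, elecsys = e),
            class = c("perisk_calpairs", "data.frame"))
}

# first-trimester window: 11w+0d .. 13w+6d
EARLY_DAY_RANGE <- c(77L, 97L)

#' Identify early-pregnancy (first trimester) records
#'
#' Early pregnancy is gestational age 11 weeks + 0 days through
#' 13 weeks + 6 days.
#'
#' @param table a cohort `data.frame` with `gest_weeks`/`gest_days` columns.
#' @return logical vector, one entry per row.
#' @export
is_early_pregnancy <- function(table) {
  gd <- gestational_day(table)
  gd >= EARLY_DAY_RANGE[1] & gd <= EARLY_DAY_RANGE[2]
}

gestational_day <- function(table) 7L * table$gest_weeks + table$gest_days
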