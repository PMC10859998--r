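#' Default model parameters
#'
#' Builds the complete set of model inputs for the liquid-biopsy-first (LB-first)
#' versus tissue-biopsy-only (TB-only) distributional cost-effectiveness model of
#' advanced NSCLC: subgroup epidemiology and baseline quality-adjusted life
#' expectancy (QALE), driver-mutation and PD-L1 prevalences, NGS test performance,
#' Weibull progression-free and overall survival parameters per therapy context,
#' hazard-ratio adjustments (mismatched therapy, turnaround-time benefit, subgroup
#' calibration, EGFR therapy adjustment), health-state utilities, unit costs under
#' a blended Medicare/commercial payer mix, and analysis settings.
#'
#' Probability vectors are stored as published (percentages rounded to 0.1%, so a
#' few sum to 0.999 or 1.001); they are renormalised when a concrete parameter
#' draw is constructed (see [point_estimate_draw()] and [draw_parameter_set()]).
#'
#' All currency values are 2022 USD, all rates are per year, and all times are in
#' years.
#'
#' @return A validated object of class `dcea_params`: a named list with elements
#'   `subgroups`, `mutations`, `pdl1`, `lb_test`, `tb_test`, `survival`,
#'   `mismatch_hr`, `tat_hr`, `utilities`, `costs` and `settings`.
#' @seealso [read_dcea_config()], [write_dcea_config()], [validate_parameters()]
#' @export
#' @examples
#' p <- dcea_parameters()
#' p$subgroups$baseline_qale
#' lifetime_risk(p, "NH-White")
dcea_parameters <- function() {
  subgroups <- data.frame(
    id = c("NH-White", "NH-Black", "Asian", "Hispanic"),
    general_share = c(0.6057, 0.1389, 0.0623, 0.1931),
    baseline_qale = c(68.798, 65.446, 74.878, 71.762),
    incidence_rate = c(23.0, 25.7, 18.0, 11.6),    # aNSCLC events per 100,000 per year
    life_expectancy = c(78.8, 74.8, 85.6, 80.2),
    insufficient_tissue = rep(0.30, 4),
    calibration_hr = c(1.345, 1.461, 1.419, 1.432),
    egfr_adjustment_hr = c(0.675, 0.675, 0.75, 0.675),
    # Optional replacement for incidence * life expectancy (e.g. 0.0095 for
    # Hispanic reproduces the published rounded lifetime risk).
    lifetime_risk_override = rep(NA_real_, 4),
    stringsAsFactors = FALSE
  )

  mut_names <- c("EGFR", "ALK", "KRAS", "ROS1", "BRAF", "NTRK", "MET", "RET")
  prevalence <- rbind(
    `NH-White` = c(0.129, 0.022, 0.138, 0.010, 0.018, 0.001, 0.029, 0.010, 0.643),
    `NH-Black` = c(0.204, 0.032, 0.097, 0.022, 0.032, 0.011, 0.000, 0.022, 0.580),
    Asian      = c(0.524, 0.048, 0.032, 0.016, 0.008, 0.000, 0.016, 0.016, 0.339),
    Hispanic   = c(0.145, 0.018, 0.055, 0.000, 0.036, 0.000, 0.036, 0.055, 0.654)
  )
  colnames(prevalence) <- c(mut_names, "none")
  mutations <- list(
    names = mut_names,
    prevalence = prevalence,
    n = c(`NH-White` = 2778, `NH-Black` = 93, Asian = 124, Hispanic = 55)
  )

  pdl1_dist <- rbind(
    `NH-White` = c(0.338, 0.338, 0.325),
    `NH-Black` = c(0.254, 0.153, 0.593),
    Asian      = c(0.336, 0.328, 0.335),
    Hispanic   = c(0.708, 0.208, 0.083)
  )
  colnames(pdl1_dist) <- c("TPS>=50", "TPS1-49", "TPS<1")
  pdl1 <- list(
    levels = colnames(pdl1_dist),
    distribution = pdl1_dist,
    n = c(`NH-White` = 305, `NH-Black` = 59, Asian = 128, Hispanic = 120)
  )

  lb_test <- data.frame(
    marker = mut_names,
    n  = c(168, 301, 147, 301, 151, 301, 143, 301),
    tp = c(0.083, 0.010, 0.327, 0.010, 0.040, 0.010, 0.028, 0.010),
    fp = c(0.006, 0.003, 0.007, 0.003, 0.007, 0.003, 0.007, 0.003),
    tn = c(0.875, 0.973, 0.585, 0.973, 0.934, 0.973, 0.937, 0.973),
    fn = c(0.036, 0.013, 0.082, 0.013, 0.020, 0.013, 0.028, 0.013),
    stringsAsFactors = FALSE
  )
  # Tissue NGS treated as near-gold-standard: one confusion vector for all
  # markers and for PD-L1, 99% sensitivity and specificity, n = 200, 50% cases.
  tb_test <- list(n = 200, tp = 0.495, fp = 0.005, tn = 0.495, fn = 0.005)

  contexts <- c(mut_names, "PD-L1>=50", "PD-L1 1-49", "wild type")
  survival <- data.frame(
    context = rep(contexts, 2),
    outcome = rep(c("PFS", "OS"), each = length(contexts)),
    log_scale = c(
      -0.5511, -0.0388, -0.1532, -0.6338, -0.1386, -1.1810, -0.7555, -0.3707,
      -0.5142,  0.2313,  0.2879,
      -1.1604, -1.0618, -0.7059, -1.6419, -1.2094, -2.2890, -1.2892, -1.7389,
      -1.1603, -0.6783, -0.6930),
    log_scale_se = c(
      0.0514, 0.0480, 0.0478, 0.1415, 0.1859, 0.4178, 0.1891, 0.1547,
      0.0954, 0.1264, 0.1254,
      0.0659, 0.0675, 0.1091, 0.2177, 0.2811, 0.6915, 0.2050, 0.2681,
      0.1114, 0.1573, 0.1594),
    shape = c(
       0.1378, -0.0542, -0.3170, -0.1189,  0.0855, -0.1083, -0.0202,  0.2126,
       0.1492, -0.0046,  0.1068,
       0.1046, -0.1311, -0.3170, -0.1847,  0.1381,  0.4589,  0.2974, -0.1642,
       0.0659,  0.0910,  0.1994),
    shape_se = c(
      0.0313, 0.0377, 0.0955, 0.1177, 0.1387, 0.3434, 0.1514, 0.1247,
      0.0628, 0.1027, 0.0968,
      0.0364, 0.0507, 0.0955, 0.1820, 0.1794, 0.3686, 0.1469, 0.2318,
      0.0761, 0.1312, 0.1290),
    correlation = c(
      -0.5863, -0.1127, 0.0000, -0.2741, -0.3093, -0.2122, 0.0313, 0.1699,
      -0.4095, 0.0789, 0.0752,
      -0.7443, -0.4514, -0.0138, -0.3954, -0.6516, -0.6907, -0.3873, 0.0811,
      -0.5963, -0.3198, -0.2920),
    stringsAsFactors = FALSE
  )

  mismatch_hr <- data.frame(
    label = c(paste("FP", mut_names),
              "TP PD-L1 + FN mut.", "FP PD-L1 + FN mut.", "FN PD-L1 + FN mut.",
              "TN PD-L1 + FN mut.", "FP PD-L1 + TN mut.", "FN PD-L1 + TN mut."),
    hr      = c(1.85, 3.45, 1.03, 1.06, 1.16, 1.30, 1.18, 1.59,
                1.34, 1.58, 1.14, 1.34, 1.18, 0.85),
    ci_low  = c(1.26, 2.13, 0.93, 0.93, 1.03, 1.10, 0.99, 1.10,
                0.89, 1.05, 0.76, 0.89, 0.97, 0.70),
    ci_high = c(2.72, 5.57, 1.14, 1.22, 1.31, 1.54, 1.39, 2.28,
                2.01, 2.37, 1.70, 2.01, 1.44, 1.03),
    stringsAsFactors = FALSE
  )

  tat_hr <- data.frame(
    scenario = c("3-week", "1-week"),
    hr = c(0.72, 0.90), ci_low = c(0.56, 0.82), ci_high = c(0.93, 0.98),
    stringsAsFactors = FALSE
  )

  utilities <- data.frame(
    state = c("pre-progression", "post-progression"),
    mean = c(0.71, 0.67), ci_low = c(0.67, 0.59), ci_high = c(0.76, 0.75),
    stringsAsFactors = FALSE
  )

  payer <- function(medicare, commercial) c(medicare = medicare, commercial = commercial)
  drug <- data.frame(
    context = contexts[c(1:8, 9, 10, 11)],
    year1       = c(178132, 205476, 185608, 221185, 313415, 406928, 185711, 237320,
                    180187, 197393, 195869),
    year2       = c(178132, 205476, 185465, 221185, 313415, 406928, 185711, 237320,
                    180187, 183115, 183383),
    year2plus   = c(178132, 205476,   7803, 221185, 313415, 406928, 185711, 237320,
                         0,   5453,   5721),
    second_line = c( 83423,  54132,  58484,  56714,  57477,  57477,  57477,  57477,
                      1400,    738,    738),
    # Second-line duration as a fraction of post-progression survival, keyed by
    # the published second-line PFS/OS ratios for the closest first-line /
    # second-line drug-class pairing.
    sl_duration_ratio = c(0.583, 0.620, 0.365, 0.583, 0.620, 0.620, 0.620, 0.620,
                          0.692, 0.365, 0.365),
    stringsAsFactors = FALSE
  )
  costs <- list(
    payer_mix = payer(0.674, 0.326),
    lb_ngs = payer(3425, 6722),
    rebiopsy = payer(324, 1628),
    rebiopsy_complication = payer(4020, 18290),
    tb_ngs = payer(1773, 4758),
    complication_prob = 0.073,
    complication_se = 0.00365,
    mgmt_pre = payer(12254, 42875),
    mgmt_pre_se = payer(613, 2144),
    mgmt_post = payer(85250, 153680),
    mgmt_post_se = payer(4263, 7684),
    drug = drug,
    bsc_fraction = 0.5
  )

  settings <- list(
    discount_rate = 0.03,
    threshold = 150000,
    atkinson_aversion = 11,
    kolm_aversion = 0.15,
    tat_scenario = "3-week",
    include_treatment_costs = FALSE,
    horizon_years = 20,
    time_step_years = 1 / 52,
    n_draws = 5000,
    weibull_form = "rate-power",          # or "ph"
    hr_application = "ph",                # or "rate"
    calibration_scope = "both",           # or "tb-informed"
    io_cap_years = Inf
  )

  params <- structure(
    list(subgroups = subgroups, mutations = mutations, pdl1 = pdl1,
         lb_test = lb_test, tb_test = tb_test, survival = survival,
         mismatch_hr = mismatch_hr, tat_hr = tat_hr, utilities = utilities,
         costs = costs, settings = settings),
    class = "dcea_params"
  )
  validate_parameters(params)
  params
}

dcea_subgroups <- function(params) params$subgroups$id

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Validate a parameter set
#'
#' Checks every structural invariant of a `dcea_params` object: population
#' shares sum to one, prevalence and PD-L1 vectors sum to one within the
#' published rounding (0.005), confusion vectors sum to one, standard errors
#' are positive, correlations lie in \[-1, 1\], hazard-ratio confidence
#' intervals bracket the point estimate, utilities are ordered on \[0, 1\],
#' the payer mix sums to one, costs are non-negative, and analysis settings
#' are admissible.
#'
#' @param params A `dcea_params` object (see [dcea_parameters()]).
#' @return `params`, invisibly, if valid; otherwise an error naming the field
#'   and the violated rule.
#' @export
validate_parameters <- function(params) {
  req <- c("subgroups", "mutations", "pdl1", "lb_test", "tb_test", "survival",
           "mismatch_hr", "tat_hr", "utilities", "costs", "settings")
  missing <- setdiff(req, names(params))
  if (length(missing))
    stop_config("configuration error: missing section(s): %s",
                paste(missing, collapse = ", "))

  sg <- params$subgroups
  if (abs(sum(sg$general_share) - 1) > 1e-9)
    stop_config("validation error: subgroups$general_share must sum to 1 (got %.10f)",
                sum(sg$general_share))
  num_cols <- c("general_share", "baseline_qale", "incidence_rate",
                "life_expectancy", "insufficient_tissue", "calibration_hr",
                "egfr_adjustment_hr")
  for (cl in num_cols)
    if (any(sg[[cl]] < 0) || any(!is.finite(sg[[cl]])))
      stop_config("validation error: subgroups$%s must be finite and non-negative", cl)
  if (any(sg$baseline_qale <= 0) || any(sg$life_expectancy <= 0))
    stop_config("validation error: baseline_qale and life_expectancy must be positive")

  prev <- params$mutations$prevalence
  if (any(abs(rowSums(prev) - 1) > 0.005))
    stop_config("validation error: mutations$prevalence rows must sum to 1 within 0.005")
  if (any(prev < 0))
    stop_config("validation error: mutations$prevalence must be non-negative")
  pd <- params$pdl1$distribution
  if (any(abs(rowSums(pd) - 1) > 0.005))
    stop_config("validation error: pdl1$distribution rows must sum to 1 within 0.005")
  if (any(pd < 0))
    stop_config("validation error: pdl1$distribution must be non-negative")

  lb <- params$lb_test
  conf <- as.matrix(lb[, c("tp", "fp", "tn", "fn")])
  if (any(abs(rowSums(conf) - 1) > 0.005))
    stop_config("validation error: lb_test confusion vectors must sum to 1 within 0.005")
  tb <- params$tb_test
  if (abs(tb$tp + tb$fp + tb$tn + tb$fn - 1) > 0.005)
    stop_config("validation error: tb_test confusion vector must sum to 1")

  sv <- params$survival
  if (any(sv$log_scale_se <= 0) || any(sv$shape_se <= 0))
    stop_config("validation error: survival parameter SEs must be positive")
  if (any(abs(sv$correlation) > 1))
    stop_config("validation error: survival$correlation must lie in [-1, 1]")

  for (nm in c("mismatch_hr", "tat_hr")) {
    h <- params[[nm]]
    if (any(h$hr <= 0))
      stop_config("validation error: %s$hr must be positive", nm)
    if (any(h$ci_low > h$hr | h$hr > h$ci_high))
      stop_config("validation error: %s confidence interval must bracket the estimate", nm)
  }

  ut <- params$utilities
  if (any(ut$mean < 0) || any(ut$mean > 1))
    stop_config("validation error: utilities must lie in [0, 1]")
  if (ut$mean[1] < ut$mean[2])
    stop_config("validation error: pre-progression utility must be >= post-progression")

  co <- params$costs
  if (abs(sum(co$payer_mix) - 1) > 1e-9)
    stop_config("validation error: costs$payer_mix must sum to 1")
  for (nm in c("lb_ngs", "rebiopsy", "rebiopsy_complication", "tb_ngs",
               "mgmt_pre", "mgmt_post"))
    if (any(co[[nm]] < 0))
      stop_config("validation error: costs$%s must be non-negative", nm)
  if (co$complication_prob < 0 || co$complication_prob > 1)
    stop_config("validation error: costs$complication_prob must be a probability")
  if (any(as.matrix(co$drug[, c("year1", "year2", "year2plus", "second_line")]) < 0))
    stop_config("validation error: drug costs must be non-negative")
  if (any(co$drug$sl_duration_ratio <= 0 | co$drug$sl_duration_ratio > 1))
    stop_config("validation error: costs$drug$sl_duration_ratio must lie in (0, 1]")
  if (co$bsc_fraction < 0 || co$bsc_fraction > 1)
    stop_config("validation error: costs$bsc_fraction must be a probability")

  st <- params$settings
  if (st$threshold <= 0)
    stop_config("validation error: settings$threshold must be positive")
  if (st$atkinson_aversion < 0 || st$atkinson_aversion == 1)
    stop_config("validation error: settings$atkinson_aversion must be >= 0 and != 1")
  if (st$kolm_aversion < 0)
    stop_config("validation error: settings$kolm_aversion must be >= 0")
  if (!st$tat_scenario %in% params$tat_hr$scenario)
    stop_config("validation error: settings$tat_scenario must be one of: %s",
                paste(params$tat_hr$scenario, collapse = ", "))
  if (!st$weibull_form %in% c("rate-power", "ph"))
    stop_config("validation error: settings$weibull_form must be 'rate-power' or 'ph'")
  if (!is.null(st$hr_application) &&
      !st$hr_application %in% c("ph", "rate"))
    stop_config("validation error: settings$hr_application must be 'ph' or 'rate'")
  if (st$horizon_years <= 0 || st$time_step_years <= 0)
    stop_config("validation error: horizon and time step must be positive")

  invisible(params)
}

#' Lifetime risk of advanced NSCLC for a subgroup
#'
#' The lifetime risk is the age-standardized incidence rate (per 100,000
#' person-years) multiplied by life expectancy at birth. Callers multiply by
#' the insufficient-tissue fraction (30%) to obtain the risk of belonging to
#' the target population of the diagnostic comparison. A per-subgroup
#' `lifetime_risk_override` in the parameter table, when non-missing, replaces
#' the computed product (used to reproduce published rounded figures).
#'
#' @param params A `dcea_params` object.
#' @param subgroup Subgroup id (e.g. `"NH-White"`); or `NULL` for all four.
#' @return Lifetime risk(s) as probabilities.
#' @export
#' @examples
#' lifetime_risk(dcea_parameters(), "NH-White")  # 0.0181
lifetime_risk <- function(params, subgroup = NULL) {
  sg <- params$subgroups
  risk <- sg$incidence_rate * 1e-5 * sg$life_expectancy
  risk <- ifelse(is.na(sg$lifetime_risk_override), risk, sg$lifetime_risk_override)
  names(risk) <- sg$id
  if (is.null(subgroup)) return(risk)
  if (!all(subgroup %in% sg$id))
    stop_config("unknown subgroup: %s", paste(setdiff(subgroup, sg$id), collapse = ", "))
  risk[subgroup]
}

#' Patient-population shares by subgroup
#'
#' Weights of the four race/ethnicity subgroups within the patient population
#' of the model (incident advanced-NSCLC cases with insufficient tissue),
#' proportional to general-population share times lifetime risk. The
#' insufficient-tissue fraction is common to all subgroups and cancels.
#'
#' @param params A `dcea_params` object.
#' @return Named numeric vector of weights summing to 1.
#' @export
patient_shares <- function(params) {
  risk <- lifetime_risk(params)
  w <- params$subgroups$general_share * risk
  if (sum(w) <= 0)
    stop_config("degenerate patient distribution: all lifetime risks are zero")
  w / sum(w)
}

#' Write a parameter set to a YAML configuration file
#'
#' The configuration mirrors the nested structure of the parameter object; the
#' packaged default reproduces every published input value. [read_dcea_config()]
#' restores an identical object.
#'
#' @param params A `dcea_params` object.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_dcea_config <- function(params, path) {
  ser <- list(
    subgroups = as.list(params$subgroups),
    mutations = list(names = params$mutations$names,
                     prevalence = mat_to_list(params$mutations$prevalence),
                     n = as.list(params$mutations$n)),
    pdl1 = list(levels = params$pdl1$levels,
                distribution = mat_to_list(params$pdl1$distribution),
                n = as.list(params$pdl1$n)),
    lb_test = as.list(params$lb_test),
    tb_test = params$tb_test,
    survival = as.list(params$survival),
    mismatch_hr = as.list(params$mismatch_hr),
    tat_hr = as.list(params$tat_hr),
    utilities = as.list(params$utilities),
    costs = lapply(params$costs, as.list),
    settings = params$settings
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Read and validate a parameter configuration
#'
#' @param path Path to a YAML configuration written by [write_dcea_config()]
#'   (or edited by hand with the same structure). `NULL` returns the packaged
#'   defaults.
#' @return A validated `dcea_params` object.
#' @export
read_dcea_config <- function(path = NULL) {
  if (is.null(path)) return(dcea_parameters())
  if (!file.exists(path)) stop_config("configuration file not found: %s", path)
  raw <- yaml::read_yaml(path)
  req <- c("subgroups", "mutations", "pdl1", "lb_test", "tb_test", "survival",
           "mismatch_hr", "tat_hr", "utilities", "costs", "settings")
  missing <- setdiff(req, names(raw))
  if (length(missing))
    stop_config("configuration error: missing key(s): %s", paste(missing, collapse = ", "))
  unlist_num <- function(x) {
    v <- unlist(x)
    storage.mode(v) <- "double"
    v
  }
  sg <- as.data.frame(raw$subgroups, stringsAsFactors = FALSE)
  sg$lifetime_risk_override <- as.numeric(sg$lifetime_risk_override)
  params <- structure(list(
    subgroups = sg,
    mutations = list(names = unlist(raw$mutations$names),
                     prevalence = list_to_mat(raw$mutations$prevalence),
                     n = unlist_num(raw$mutations$n)),
    pdl1 = list(levels = unlist(raw$pdl1$levels),
                distribution = list_to_mat(raw$pdl1$distribution),
                n = unlist_num(raw$pdl1$n)),
    lb_test = as.data.frame(raw$lb_test, stringsAsFactors = FALSE),
    tb_test = raw$tb_test,
    survival = as.data.frame(raw$survival, stringsAsFactors = FALSE),
    mismatch_hr = as.data.frame(raw$mismatch_hr, stringsAsFactors = FALSE),
    tat_hr = as.data.frame(raw$tat_hr, stringsAsFactors = FALSE),
    utilities = as.data.frame(raw$utilities, stringsAsFactors = FALSE),
    costs = lapply(stats::setNames(names(raw$costs), names(raw$costs)), function(nm) {
      x <- raw$costs[[nm]]
      if (nm == "drug") as.data.frame(x, stringsAsFactors = FALSE)
      else if (is.list(x)) unlist_num(x) else x
    }),
    settings = raw$settings
  ), class = "dcea_params")
  validate_parameters(params)
  params
}

mat_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(out) <- rownames(m)
  out
}

list_to_mat <- function(l) {
  m <- do.call(rbind, lapply(l, function(r) unlist(r)))
  rownames(m) <- names(l)
  m
}

#' @export
print.dcea_params <- function(x, ...) {
  cat("Distributional cost-effectiveness model parameters\n")
  cat(sprintf("  Subgroups: %s\n", paste(x$subgroups$id, collapse = ", ")))
  cat(sprintf("  Driver mutations: %s\n", paste(x$mutations$names, collapse = ", ")))
  cat(sprintf("  Therapy contexts with survival curves: %d\n",
              length(unique(x$survival$context))))
  cat(sprintf("  Base-case settings: %.0f%%/yr discount, $%s/QALY threshold, Atkinson %g, Kolm %g, TAT %s\n",
              100 * x$settings$discount_rate,
              format(x$settings$threshold, big.mark = ","),
              x$settings$atkinson_aversion, x$settings$kolm_aversion,
              x$settings$tat_scenario))
  invisible(x)
}
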