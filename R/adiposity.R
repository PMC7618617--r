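#' Adiposity index panel
#'
#' Ten anthropometric and lipid-based adiposity measures computed from
#' weight, height, waist circumference (WC), sagittal abdominal diameter
#' (SAD), triglycerides (TG), HDL cholesterol and (where available)
#' DXA total fat mass:
#'
#' * BMI = weight / height^2 (kg/m^2), rounded to one decimal;
#' * WC (cm) and WHtR = WC / height (both in cm, dimensionless);
#' * ABSI = WC / (BMI^(2/3) * height^(1/2)), SI units (WC and height in m);
#' * BRI = 364.2 - 365.5 * sqrt(1 - (WC/2pi)^2 / (0.5 height)^2), WC and
#'   height in cm (body cross-section treated as an ellipse);
#' * VAI, sex-specific:
#'   men (WC / (39.68 + 1.88 BMI)) * (TG/1.03) * (1.31/HDL),
#'   women (WC / (36.58 + 1.89 BMI)) * (TG/0.81) * (HDL term 1.52/HDL),
#'   WC in cm, lipids in mmol/L;
#' * LAP = (WC - 65) * TG for men, (WC - 58) * TG for women;
#' * FMI = fat mass / height^2 (kg/m^2), percent body fat, SAD (cm) and
#'   SADHtR = SAD / height (cm/cm).
#'
#' Fat-mass-derived measures are missing whenever total fat mass is.
#'
#' @name adiposity_panel
NULL

#' Body mass index
#'
#' Weight in kilograms divided by height in metres squared, rounded half
#' away from zero to one decimal place.
#'
#' @param weight_kg,height_m positive numerics (vectorised).
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0 | height_m <= 0, na.rm = TRUE)) {
    stop("weight and height must be positive")
  }
  round_half_up(weight_kg / height_m^2, 1)
}

#' Compute the full adiposity panel for one or more participants
#'
#' @param anthro data.frame with columns `sex` ("Male"/"Female"),
#'   `weight_kg`, `height_m`, `wc_cm`, `sad_cm`, `tg_mmol_l`, `hdl_mmol_l`,
#'   and optionally `fat_mass_kg` (NA allowed) and `participant_id`.
#' @return data.frame with columns `bmi`, `wc`, `whtr`, `absi`, `bri`,
#'   `vai`, `lap`, `sad`, `sadhtr`, `fat_mass`, `fmi`, `pct_fat` (plus
#'   `participant_id` when present in the input).
#' @export
compute_indices <- function(anthro) {
  req <- c("sex", "weight_kg", "height_m", "wc_cm", "sad_cm",
           "tg_mmol_l", "hdl_mmol_l")
  miss <- setdiff(req, names(anthro))
  if (length(miss)) stop("anthropometry missing columns: ", paste(miss, collapse = ", "))
  with(anthro, {
    if (any(height_m <= 0, na.rm = TRUE)) stop("height must be positive")
    if (any(hdl_mmol_l <= 0, na.rm = TRUE)) stop("HDL must be positive")
    male <- sex == "Male"
    bmi <- compute_bmi(weight_kg, height_m)
    height_cm <- height_m * 100
    whtr <- wc_cm / height_cm
    absi <- (wc_cm / 100) / (bmi^(2 / 3) * height_m^(1 / 2))
    ecc2 <- (wc_cm / (2 * pi))^2 / (0.5 * height_cm)^2
    bri <- 364.2 - 365.5 * sqrt(pmax(0, 1 - ecc2))
    vai <- ifelse(male,
      (wc_cm / (39.68 + 1.88 * bmi)) * (tg_mmol_l / 1.03) * (1.31 / hdl_mmol_l),
      (wc_cm / (36.58 + 1.89 * bmi)) * (tg_mmol_l / 0.81) * (hdl_mmol_l / 1.52)^-1)
    lap <- ifelse(male, (wc_cm - 65) * tg_mmol_l, (wc_cm - 58) * tg_mmol_l)
    fat_mass <- if ("fat_mass_kg" %in% names(anthro)) fat_mass_kg else
      rep(NA_real_, length(bmi))
    fmi <- fat_mass / height_m^2
    pct_fat <- 100 * fat_mass / weight_kg
    out <- data.frame(
      bmi = bmi, wc = wc_cm, whtr = whtr, absi = absi, bri = bri,
      vai = vai, lap = lap, sad = sad_cm, sadhtr = sad_cm / height_cm,
      fat_mass = fat_mass, fmi = fmi, pct_fat = pct_fat)
    if ("participant_id" %in% names(anthro)) {
      out <- cbind(participant_id = anthro$participant_id, out)
    }
    out
  })
}

#' Percentile winsorization
#'
#' Caps values below the lower percentile and above the upper percentile at
#' those thresholds (quantiles by linear interpolation between order
#' statistics, type 7). Applied to BMI, WC, total fat mass, percent fat and
#' SAD to limit the influence of extreme values. Idempotent and
#' order-preserving.
#'
#' @param values numeric vector (NAs passed through).
#' @param lower,upper percentile probabilities.
#' @param bounds optional fixed `c(low, high)` caps; when supplied the
#'   percentiles are not re-estimated (capping at fixed bounds is exactly
#'   idempotent).
#' @return list with `values` (capped), `p_lower`, `p_upper`, `n_capped`.
#' @export
winsorize_percentile <- function(values, lower = 0.01, upper = 0.99,
                                 bounds = NULL) {
  if (all(is.na(values))) stop("all values missing")
  q <- if (is.null(bounds)) {
    quantile(values, c(lower, upper), na.rm = TRUE, type = 7, names = FALSE)
  } else bounds
  capped <- pmin(pmax(values, q[1]), q[2])
  list(values = capped, p_lower = q[1], p_upper = q[2],
       n_capped = sum(capped != values, na.rm = TRUE))
}

#' Pairwise Pearson correlations between adiposity measures
#'
#' @param panels data.frame of panel columns (as from [compute_indices()]);
#'   non-numeric columns are dropped. Pairwise-complete observations.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_summary <- function(panels) {
  panels <- as.data.frame(panels)
  num <- panels[vapply(panels, is.numeric, logical(1))]
  stats::cor(as.matrix(num), use = "pairwise.complete.obs", method = "pearson")
}
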