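## Adjustment of raw growth measurements to the 100 kg reference weight,
## with the sex-specific correction factors used by the Canadian swine
## genetic evaluation (boar-track vs gilt-track coefficients).

.sexFactor <- function(sex) {
  sx <- toupper(as.character(sex))
  ok <- sx %in% c("M", "F")
  if (any(!ok)) stop("sex must be 'M' (male/boar) or 'F' (female/gilt)")
  sx
}

#' Adjust age at a measured weight to age at 100 kg
#'
#' Days of age are corrected to the day the animal would have reached the
#' 100 kg reference weight, using a sex-specific growth correction factor
#' proportional to the animal's own weight-for-age ratio:
#' \deqn{AGE_{100} = age - \frac{weight - 100}{CF_1}, \quad
#'   CF_1 = \frac{weight}{age} \times k_{sex}}
#' with k = 1.826 for males and k = 1.715 for females.
#'
#' @param age measured age in days (> 0).
#' @param weight measured live weight in kg (> 0).
#' @param sex "M" or "F" (recycled).
#' @return adjusted age in days (AGE, "days to 100 kg").
#' @examples
#' adjustAge(160, 110, "M") # ~152.0 days
#' @export
adjustAge <- function(age, weight, sex) {
  sx <- .sexFactor(sex)
  if (any(age <= 0)) stop("measured age must be strictly positive")
  if (any(weight <= 0)) stop("measured weight must be strictly positive")
  k <- ifelse(sx == "M", 1.826, 1.715)
  cf1 <- weight / age * k
  age - (weight - 100) / cf1
}

#' Average daily gain standardized to 100 kg
#'
#' ADG is defined as 100 kg divided by the adjusted age, reported in grams
#' per day, so `adjustADG(age100) * age100 == 1e5` grams always holds.
#'
#' @param age100 age at 100 kg in days (> 0), as returned by [adjustAge()].
#' @return average daily gain in g/day.
#' @examples
#' adjustADG(200) # 500 g/day
#' @export
adjustADG <- function(age100) {
  if (any(age100 <= 0)) stop("adjusted age must be strictly positive")
  1e5 / age100
}

#' Adjust ultrasound backfat thickness to 100 kg
#'
#' \deqn{BF_{100} = BF \times \frac{A}{A + B (weight - 100)}}
#' with A = 13.47, B = 0.1115 for males and A = 15.65, B = 0.1566 for
#' females (CCSI weight-adjustment coefficients). Exact identity at 100 kg.
#'
#' @param bf measured backfat in mm (>= 0).
#' @param weight measured live weight in kg.
#' @param sex "M" or "F".
#' @return adjusted backfat in mm.
#' @examples
#' adjustBF(10, 110, "M") # ~9.24 mm
#' @export
adjustBF <- function(bf, weight, sex) {
  sx <- .sexFactor(sex)
  if (any(bf < 0)) stop("backfat must be non-negative")
  A <- ifelse(sx == "M", 13.47, 15.65)
  B <- ifelse(sx == "M", 0.1115, 0.1566)
  den <- A + B * (weight - 100)
  if (any(den <= 0)) stop("adjustment denominator non-positive (weight too low)")
  bf * A / den
}

#' Adjust ultrasound loin muscle depth to 100 kg
#'
#' \deqn{LMD_{100} = LMD \times \frac{a}{a + b (weight - 100)}}
#' with a = 50.52 (males) / 52.01 (females) and b = 0.228 for both sexes.
#'
#' @param lmd measured loin muscle depth in mm (>= 0).
#' @param weight measured live weight in kg.
#' @param sex "M" or "F".
#' @return adjusted loin muscle depth in mm.
#' @examples
#' adjustLMD(50, 110, "M") # ~47.84 mm
#' @export
adjustLMD <- function(lmd, weight, sex) {
  sx <- .sexFactor(sex)
  if (any(lmd < 0)) stop("loin muscle depth must be non-negative")
  a <- ifelse(sx == "M", 50.52, 52.01)
  b <- 0.228
  den <- a + b * (weight - 100)
  if (any(den <= 0)) stop("adjustment denominator non-positive (weight too low)")
  lmd * a / den
}

#' Predicted lean meat percentage at 100 kg
#'
#' Linear prediction from the 100 kg-adjusted backfat and loin muscle depth:
#' \deqn{LMP = 61.21920 - 0.77665 \times BF_{100} + 0.15239 \times LMD_{100}}
#'
#' @param bf100 backfat adjusted to 100 kg, mm.
#' @param lmd100 loin muscle depth adjusted to 100 kg, mm.
#' @return lean meat percentage.
#' @examples
#' computeLMP(9.52, 48.49)
#' @export
computeLMP <- function(bf100, lmd100) {
  if (any(!is.finite(bf100)) || any(!is.finite(lmd100))) {
    stop("inputs must be finite")
  }
  61.21920 - 0.77665 * bf100 + 0.15239 * lmd100
}

#' Adjust a table of raw measurements to the 100 kg reference
#'
#' Applies [adjustAge()], [adjustADG()], [adjustBF()], [adjustLMD()] and
#' [computeLMP()] row-wise. LMP is computed from the *adjusted* BF and LMD.
#' Animals weighed outside the 100 +/- 5 kg ultrasound window are flagged
#' (`offTarget`) but never dropped.
#'
#' @param raw data.frame with columns `id`, `sex`, `age`, `weight` and
#'   optionally `bf`, `lmd` (ultrasound measurements in mm).
#' @return data.frame with one row per animal: `id`, `sex`, `age100`,
#'   `adg100`, and when ultrasound columns are present `bf100`, `lmd100`,
#'   `lmp100`, plus the `offTarget` flag.
#' @export
adjustTraits <- function(raw) {
  need <- c("id", "sex", "age", "weight")
  if (!all(need %in% names(raw))) {
    stop("raw measurements need columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    id = raw$id,
    sex = .sexFactor(raw$sex),
    age100 = adjustAge(raw$age, raw$weight, raw$sex),
    stringsAsFactors = FALSE
  )
  out$adg100 <- adjustADG(out$age100)
  if (all(c("bf", "lmd") %in% names(raw))) {
    out$bf100 <- adjustBF(raw$bf, raw$weight, raw$sex)
    out$lmd100 <- adjustLMD(raw$lmd, raw$weight, raw$sex)
    out$lmp100 <- computeLMP(out$bf100, out$lmd100)
  }
  out$offTarget <- abs(raw$weight - 100) > 5
  out
}
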