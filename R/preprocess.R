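#' Standardize a variable to z-scores
#'
#' Centres by the sample mean and scales by the sample standard deviation
#' (n - 1 denominator), returning both the standardized values and the
#' parameters needed to project new data onto the same scale or invert the
#' transform.
#'
#' @param x Numeric vector, length >= 2, finite, non-constant.
#' @return List with `values` (mean 0, sample SD 1) and `params`, a list
#'   with elements `center` and `scale`.
#' @export
zscore <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("cannot z-score a constant vector (sd = 0)", call. = FALSE)
  m <- mean(x)
  list(values = (x - m) / s, params = list(center = m, scale = s))
}

#' Apply or invert a stored standardization
#'
#' @param x Numeric vector.
#' @param params A `params` element as returned by [zscore()].
#' @return `apply_zscore` projects raw values onto the stored scale;
#'   `destandardize` maps z-scores back to the raw scale.
#' @export
apply_zscore <- function(x, params) (x - params$center) / params$scale

#' @rdname apply_zscore
#' @export
destandardize <- function(x, params) x * params$scale + params$center

design_colnames <- c("age", "sex_girl", "bmi_normal", "bmi_overweight",
                     "bmi_obese", "predictor", "pred_x_normal",
                     "pred_x_overweight", "pred_x_obese")

#' Build the regression design matrix
#'
#' Encodes the linear model's nine predictor columns: standardized age,
#' sex (boys = 0, girls = 1), three BMI-group indicators with underweight
#' as the reference level, the standardized predictor (CMJ height or the
#' potential-energy index), and the predictor-by-group interactions
#' (elementwise product of the standardized predictor and each indicator).
#' Indicators are left as 0/1; continuous variables are z-scored. The
#' intercept is handled by the model, not stored as a column.
#'
#' @param metrics A [derive_metrics()] table (columns `sex`, `age_years`,
#'   `bmi_group`, and the predictor column).
#' @param predictor `"cmj_height"` (uses `cmj_cm`) or `"pe_cmj"` (uses
#'   `pe_operational`; the physical convention differs only by the constant
#'   factor g, which z-scoring removes, so the fitted model is identical).
#' @param standardize_age Whether age is z-scored like the other continuous
#'   variables (default TRUE; switchable because the source analysis does
#'   not state it explicitly).
#' @return Object of class `design_matrix`: list with the n x 9 numeric
#'   matrix `X`, the `predictor` label, a `coding` record of reference
#'   levels, and `standardization` parameters for age and predictor.
#' @export
encode_design <- function(metrics,
                          predictor = c("cmj_height", "pe_cmj"),
                          standardize_age = TRUE) {
  predictor <- match.arg(predictor)
  req <- c("sex", "age_years", "bmi_group")
  missing_cols <- setdiff(req, names(metrics))
  if (length(missing_cols) > 0L) {
    stop("metrics are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(metrics$sex %in% c("boy", "girl"))) {
    stop("unknown sex label; expected 'boy'/'girl'", call. = FALSE)
  }
  grp <- as.character(metrics$bmi_group)
  if (any(is.na(grp)) || !all(grp %in% bmi_groups())) {
    stop("unknown BMI group label; expected one of: ",
         paste(bmi_groups(), collapse = ", "), call. = FALSE)
  }
  pred_col <- switch(predictor, cmj_height = "cmj_cm", pe_cmj = "pe_operational")
  if (!(pred_col %in% names(metrics))) {
    stop("metrics are missing the predictor column '", pred_col, "'",
         call. = FALSE)
  }

  n <- nrow(metrics)
  if (standardize_age) {
    age_std <- zscore(metrics$age_years)
    age_col <- age_std$values
    age_params <- age_std$params
  } else {
    age_col <- metrics$age_years
    age_params <- NULL
  }
  pred_std <- zscore(metrics[[pred_col]])

  X <- matrix(0, nrow = n, ncol = 9L, dimnames = list(NULL, design_colnames))
  X[, "age"] <- age_col
  X[, "sex_girl"] <- as.numeric(metrics$sex == "girl")
  X[, "bmi_normal"] <- as.numeric(grp == "normal")
  X[, "bmi_overweight"] <- as.numeric(grp == "overweight")
  X[, "bmi_obese"] <- as.numeric(grp == "obese")
  X[, "predictor"] <- pred_std$values
  X[, "pred_x_normal"] <- pred_std$values * X[, "bmi_normal"]
  X[, "pred_x_overweight"] <- pred_std$values * X[, "bmi_overweight"]
  X[, "pred_x_obese"] <- pred_std$values * X[, "bmi_obese"]

  structure(
    list(X = X,
         predictor = predictor,
         coding = list(sex = c(boy = 0, girl = 1),
                       bmi_reference = "underweight"),
         standardization = list(age = age_params, predictor = pred_std$params),
         standardize_age = standardize_age),
    class = "design_matrix"
  )
}

# accept either a design_matrix object or a bare numeric matrix
as_design_matrix <- function(design) {
  X <- if (inherits(design, "design_matrix")) design$X else design
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("design must be a design_matrix or a numeric matrix", call. = FALSE)
  }
  if (ncol(X) != 9L) {
    stop("design matrix must have 9 columns (age, sex, 3 BMI indicators, ",
         "predictor, 3 interactions); got ", ncol(X), call. = FALSE)
  }
  X
}
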