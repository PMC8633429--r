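# Environmental-variable preparation: aridity index, Hargreaves-Samani
# potential evapotranspiration, and the variance-inflation screen.

#' UNEP aridity index
#'
#' \eqn{AI = MAP / PET}. Values near zero indicate hyper-aridity;
#' \eqn{AI \ge 0.65} is classified as humid. With `classes = TRUE` the full
#' UNEP breakdown is returned (hyper-arid < 0.05, arid < 0.20, semi-arid
#' < 0.50, dry subhumid < 0.65, humid otherwise).
#'
#' @param MAP annual precipitation, mm.
#' @param PET annual potential evapotranspiration, mm; must be positive.
#' @param classes return the five-class UNEP label instead of the binary
#'   humid / not-humid label.
#' @return data.frame with columns `AI` and `class`.
#' @examples
#' aridity_index(MAP = 650, PET = 1000)
#' @export
aridity_index <- function(MAP, PET, classes = FALSE) {
  .check_nonnegative(MAP, "MAP")
  if (any(!is.na(PET) & PET <= 0))
    stop("'PET' must be positive", call. = FALSE)
  AI <- MAP / PET
  label <- if (classes) {
    cut(AI, breaks = c(-Inf, 0.05, 0.20, 0.50, 0.65, Inf),
        labels = c("hyper-arid", "arid", "semi-arid", "dry subhumid", "humid"),
        right = FALSE)
  } else {
    ifelse(AI >= 0.65, "humid", "not humid")
  }
  data.frame(AI = AI, class = as.character(label))
}

#' Hargreaves-Samani potential evapotranspiration
#'
#' Per-period PET (mm/day) from the temperature-based Hargreaves-Samani
#' formula, \eqn{PET = 0.0023 \, R_a (T_{mean} + 17.8) \sqrt{T_{max} -
#' T_{min}}}, scaled by the number of days in each period and summed to an
#' annual total. `Ra` is extraterrestrial radiation expressed as its
#' evaporation equivalent (mm/day).
#'
#' @param Tmean,Tmax,Tmin per-period mean / maximum / minimum air
#'   temperature, degrees C. `Tmax >= Tmin` is required.
#' @param Ra per-period extraterrestrial radiation, mm/day equivalent.
#' @param days number of days in each period; defaults to calendar month
#'   lengths when 12 periods are supplied, otherwise to 1 (daily input).
#' @return list with `pet_total` (mm/year) and `pet_period` (mm per period).
#' @export
hargreaves_pet <- function(Tmean, Tmax, Tmin, Ra, days = NULL) {
  n <- length(Tmean)
  if (length(Tmax) != n || length(Tmin) != n || length(Ra) != n)
    stop("'Tmean', 'Tmax', 'Tmin' and 'Ra' must have equal length",
         call. = FALSE)
  if (any(Tmax < Tmin))
    stop("'Tmax' must be >= 'Tmin' in every period", call. = FALSE)
  .check_nonnegative(Ra, "Ra")
  if (is.null(days))
    days <- if (n == 12L) c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
            else rep(1, n)
  pet_day <- 0.0023 * Ra * (Tmean + 17.8) * sqrt(Tmax - Tmin)
  pet_day <- pmax(pet_day, 0)  # Tmean below -17.8 cannot evaporate negatively
  pet_period <- pet_day * days
  list(pet_total = sum(pet_period), pet_period = pet_period)
}

.vif_values <- function(df) {
  vapply(seq_along(df), function(i) {
    fit <- stats::lm(df[[i]] ~ ., data = df[-i])
    # collinear candidates legitimately produce perfect fits here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Iterative variance-inflation-factor screen
#'
#' Repeatedly removes the variable with the largest variance inflation
#' factor, \eqn{VIF_i = 1/(1 - R^2_i)} with \eqn{R^2_i} from regressing
#' variable *i* on all others, until every VIF is at or below `threshold`.
#' A perfectly collinear variable has infinite VIF and is removed first.
#' Tie-break (including multiple infinite VIFs): the variable occurring
#' later in the input column order is removed, which makes the screen
#' deterministic.
#'
#' @param env data.frame of numeric candidate variables (plots in rows).
#' @param threshold maximum tolerated VIF (default 10).
#' @return list with `retained` (column names kept), `removed` (in removal
#'   order), `vif` (named VIFs of the retained set) and `steps`
#'   (data.frame log of each removal with the VIF that triggered it).
#' @export
select_variables_vif <- function(env, threshold = 10) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  env <- env[num]
  if (ncol(env) < 2L) stop("need at least two numeric variables", call. = FALSE)
  if (nrow(env) < 3L) stop("need at least three plots", call. = FALSE)
  if (anyNA(env)) stop("missing values in 'env'", call. = FALSE)

  order0 <- names(env)
  removed <- character(0)
  trigger <- numeric(0)
  current <- env
  repeat {
    if (ncol(current) < 2L) {
      vifs <- setNames(numeric(ncol(current)), names(current))
      break
    }
    vifs <- .vif_values(current)
    names(vifs) <- names(current)
    if (all(vifs <= threshold)) break
    worst <- max(vifs)
    cand <- which(vifs == worst)
    # later in original input order wins removal
    drop_i <- cand[which.max(match(names(current)[cand], order0))]
    removed <- c(removed, names(current)[drop_i])
    trigger <- c(trigger, worst)
    current <- current[-drop_i]
  }
  list(retained = names(current), removed = removed, vif = vifs,
       steps = data.frame(removed = removed, vif = trigger))
}
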