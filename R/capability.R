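#' Cap a raw intensity-of-use index at 1
#'
#' Raw intensity indices are ratios of accessible resource to use. Values
#' larger than 1 are set equal to 1, meaning no resource depletion due to
#' use; values between 0 and 1 (use exceeds renewal) pass through. The
#' `Inf` sentinel produced for zero use maps to 1.
#'
#' @param raw Raw ratio(s), `Inf` allowed; `NA` propagates (missing data).
#' @return Capped index in \[0, 1\].
#' @export
cap_index <- function(raw) {
  if (any(raw < 0, na.rm = TRUE)) stop_encar("raw intensity must be >= 0")
  pmin(raw, 1)
}

#' Ecological unit value of an account
#'
#' Arithmetic mean (configurable weights) of the capped intensity-of-use
#' index and the ecosystem health index; `NA` in either yields `NA`
#' (missing data are never imputed).
#'
#' @param capped_intensity,health Indices in \[0, 1\].
#' @param w_intensity Weight of the intensity index in \[0, 1\]; health gets
#'   the complement. Default 0.5 (plain average).
#' @return Unit value in \[0, 1\].
#' @export
unit_value <- function(capped_intensity, health, w_intensity = 0.5) {
  chk01(capped_intensity, "capped_intensity", na_ok = TRUE)
  chk01(health, "health", na_ok = TRUE)
  chk01(w_intensity, "w_intensity")
  w_intensity * capped_intensity + (1 - w_intensity) * health
}

#' Total ecosystem capability (TEC) in ECU
#'
#' Sum of the ecological unit values of water (UVW), bio-carbon (UVC) and
#' ecosystem infrastructure (UVEI), expressed in ecological capability units
#' per SELU, so TEC lies in \[0, 3\]. Missing components are excluded from
#' the sum and flagged, never imputed.
#'
#' @param uvw,uvc,uvei Unit values in \[0, 1\] or `NA` (vectorised).
#' @return data.frame with `tec` (partial sum over present components),
#'   `n_components` and `missing` (comma-separated component flags, `""` if
#'   complete).
#' @export
total_capability <- function(uvw, uvc, uvei) {
  chk01(uvw, "uvw", na_ok = TRUE); chk01(uvc, "uvc", na_ok = TRUE)
  chk01(uvei, "uvei", na_ok = TRUE)
  m <- cbind(water = uvw, carbon = uvc, infrastructure = uvei)
  tec <- rowSums(m, na.rm = TRUE)
  nc <- rowSums(!is.na(m))
  missing <- apply(m, 1, function(r)
    paste(colnames(m)[is.na(r)], collapse = ","))
  data.frame(tec = tec, n_components = nc, missing = missing)
}

#' Per-SELU capability records
#'
#' Assembles, for each SELU and each thematic account, the raw intensity,
#' the capped intensity, the health index and the unit value, and sums the
#' unit values into total ecosystem capability (ECU).
#'
#' @param selus SELU table ([build_selus()]).
#' @param water,carbon,infrastructure data.frames with columns `selu_id`,
#'   `raw_intensity`, `health` (use `NA` for missing data).
#' @param w_intensity Passed to [unit_value()].
#' @return data.frame (one row per SELU) with per-account columns
#'   `raw_*`, `capped_*`, `health_*`, `uv_*`, plus `tec`, `missing`.
#' @export
capability_table <- function(selus, water, carbon, infrastructure,
                             w_intensity = 0.5) {
  pull <- function(d, nm) {
    i <- match(selus$selu_id, d$selu_id)
    list(raw = d$raw_intensity[i], health = d$health[i])
  }
  acc <- list(water = pull(water), carbon = pull(carbon),
              infrastructure = pull(infrastructure))
  out <- data.frame(selu_id = selus$selu_id, dlct_code = selus$dlct_code,
                    area_ha = selus$area_ha)
  uv <- list()
  for (a in names(acc)) {
    capped <- cap_index(acc[[a]]$raw)
    uv[[a]] <- unit_value(capped, acc[[a]]$health, w_intensity)
    out[[paste0("raw_", a)]] <- acc[[a]]$raw
    out[[paste0("capped_", a)]] <- capped
    out[[paste0("health_", a)]] <- acc[[a]]$health
    out[[paste0("uv_", a)]] <- uv[[a]]
  }
  tc <- total_capability(uv$water, uv$carbon, uv$infrastructure)
  cbind(out, tc)
}

#' Watershed summary of capability records
#'
#' Area-weighted means of every index and of TEC across SELUs; with two
#' epochs supplied, also the average yearly rate of change.
#'
#' @param records Capability table ([capability_table()]).
#' @param records_t1 Optional later-epoch capability table (same SELUs).
#' @param n_years Period length, required with `records_t1`.
#' @return Named list: `means` (named vector) and, with two epochs,
#'   `change_per_yr`.
#' @export
watershed_summary <- function(records, records_t1 = NULL, n_years = NULL) {
  wmean <- function(d) {
    num <- vapply(d, is.numeric, logical(1)) &
      !names(d) %in% c("selu_id", "dlct_code", "area_ha", "n_components")
    w <- d$area_ha / sum(d$area_ha)
    vapply(d[num], function(x) {
      keep <- is.finite(x)
      if (!any(keep)) return(NA_real_)
      sum(w[keep] * x[keep]) / sum(w[keep])
    }, numeric(1))
  }
  out <- list(means = wmean(records))
  if (!is.null(records_t1)) {
    if (is.null(n_years)) stop_encar("n_years required for change rates")
    m1 <- wmean(records_t1)
    common <- intersect(names(out$means), names(m1))
    out$change_per_yr <- vapply(common, function(k)
      yearly_change(out$means[[k]], m1[[k]], n_years), numeric(1))
  }
  out
}

#' Detect degradation hotspots between two epochs
#'
#' Flags SELUs where, at the final epoch, any capped intensity index is
#' below 1 (use exceeds renewal) and its decline since the opening epoch
#' exceeds a threshold. Deterministic; sorted by decline, largest first.
#'
#' @param records_t0,records_t1 Capability tables for the two epochs.
#' @param threshold Minimum decline of a capped index, default 0.1.
#' @return data.frame `selu_id`, `account`, `decline`, sorted by decline.
#' @export
hotspot_detection <- function(records_t0, records_t1, threshold = 0.1) {
  stopifnot(identical(records_t0$selu_id, records_t1$selu_id))
  rows <- list()
  for (a in c("water", "carbon", "infrastructure")) {
    c0 <- records_t0[[paste0("capped_", a)]]
    c1 <- records_t1[[paste0("capped_", a)]]
    decline <- c0 - c1
    hit <- which(!is.na(c1) & c1 < 1 & !is.na(decline) & decline > threshold)
    if (length(hit))
      rows[[a]] <- data.frame(selu_id = records_t0$selu_id[hit], account = a,
                              decline = decline[hit])
  }
  if (!length(rows))
    return(data.frame(selu_id = integer(), account = character(),
                      decline = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(-out$decline, out$selu_id, out$account), , drop = FALSE]
}
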