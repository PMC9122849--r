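# Floral resource availability index:
#   fai[l, t] = n * sum_p cr[p, l] * vr[p, t]
# where cr[p, l] is landscape l's share of the across-landscape cover of
# plants providing pollen type p, and vr[p, t] is the share of pollen type p
# in the pollinator's diet (by pollen volume) during period t. With both
# shares summing to 1, the index averages 1 across landscapes: 1 means
# landscape-average pollen availability for the period.

#' Diet weights vr for one period
#'
#' `vr[p, t]` is the pollen volume of type `p` in period `t` divided by the
#' total volume over the types included for that period. The `"pooled"`
#' period sums each type's volumes across the seasonal periods before
#' normalizing. Which types belong to a period is read from the diet table's
#' rows (a type can be listed with volume 0), or overridden via
#' `included_types`; an included type absent from the diet gets weight 0 with
#' a warning.
#'
#' @param diet Validated pollen-diet table.
#' @param period One of [fai_periods()].
#' @param included_types Optional character vector restricting (or extending)
#'   the types considered.
#' @return List of class `fai_vr`: `period`, `weights` (named, sums to 1),
#'   `included_types`.
#' @export
compute_vr <- function(diet, period, included_types = NULL) {
  diet <- validate_diet(diet)
  period <- match.arg(period, fai_periods())
  if (period == "pooled") {
    vols <- tapply(diet$volume, diet$pollen_type, sum)
  } else {
    d <- diet[diet$period == period, ]
    vols <- tapply(d$volume, d$pollen_type, sum)
  }
  vols <- stats::setNames(as.numeric(vols), names(vols))
  if (is.null(included_types)) included_types <- names(vols)
  absent <- setdiff(included_types, names(vols))
  if (length(absent) > 0L) {
    warning("pollen type(s) not in the diet for period '", period,
            "', assigned weight 0: ", paste(absent, collapse = ", "),
            call. = FALSE)
    vols[absent] <- 0
  }
  vols <- vols[included_types]
  total <- sum(vols)
  if (total <= 0) {
    stop("total diet volume is zero for period '", period, "'", call. = FALSE)
  }
  structure(list(period = period, weights = vols / total,
                 included_types = included_types),
            class = "fai_vr")
}

#' Cover shares cr for one pollen type
#'
#' Sums the cover of all species providing the pollen type within each
#' landscape, then divides by the grand total across landscapes. Landscapes
#' with no cover record get share 0. A type with zero total cover is flagged
#' (`zero_cover = TRUE`, all shares 0): its `cr` is undefined (0/0).
#'
#' @param cover Validated cover table.
#' @param plants Validated annotation table.
#' @param pollen_type Type identifier.
#' @param landscape_ids Landscapes to report (default: all in `cover`).
#' @return List of class `fai_cr`: `pollen_type`, `shares` (named by
#'   landscape, sums to 1 unless zero-cover), `n`, `zero_cover`.
#' @export
compute_cr <- function(cover, plants, pollen_type, landscape_ids = NULL) {
  plants <- validate_plants(plants)
  cover <- validate_cover(cover, plants)
  if (is.null(landscape_ids)) landscape_ids <- sort(unique(cover$landscape_id))
  spp <- plants$species[plants$pollen_type == pollen_type]
  sub <- cover[cover$species %in% spp, ]
  by_l <- tapply(sub$cover_m2, factor(sub$landscape_id, levels = landscape_ids),
                 sum, default = 0)
  by_l <- stats::setNames(as.numeric(by_l), landscape_ids)
  total <- sum(by_l)
  zero <- total <= 0
  structure(list(pollen_type = pollen_type,
                 shares = if (zero) by_l else by_l / total,
                 n = length(landscape_ids), zero_cover = zero),
            class = "fai_cr")
}

#' Evaluate the index from cover shares and diet weights
#'
#' Computes `fai[l] = n * sum_p cr[p, l] * vr[p]` for one period.
#' `diet_weights` must already be normalized over the types supplied in
#' `cover_shares` (the higher-level [fai_table()] takes care of dropping
#' zero-cover types and renormalizing).
#'
#' @param cover_shares List of `fai_cr` objects, one per pollen type.
#' @param diet_weights An `fai_vr` object whose weight names match the cover
#'   shares' pollen types.
#' @param n Number of landscapes (must match the shares).
#' @return Named numeric vector of fai values, mean 1 across landscapes.
#' @export
compute_fai <- function(cover_shares, diet_weights, n) {
  types <- vapply(cover_shares, `[[`, "", "pollen_type")
  ids <- names(cover_shares[[1L]]$shares)
  for (cs in cover_shares) {
    if (cs$n != n || !identical(names(cs$shares), ids)) {
      stop("cover shares disagree with n = ", n, " landscapes", call. = FALSE)
    }
  }
  w <- diet_weights$weights
  miss <- setdiff(types, names(w))
  if (length(miss) > 0L) {
    stop("diet weights missing for pollen type(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cr <- vapply(cover_shares, `[[`, numeric(n), "shares")  # n x P
  fai <- n * as.numeric(cr %*% w[types])
  stats::setNames(fai, ids)
}

# Weights actually used for one period: positive-cover mapped types, with
# zero-cover types dropped and weights renormalized (default), or the raw
# diet shares over all listed types (vr_include_unmapped = TRUE).
period_weights <- function(bundle, period, vr_include_unmapped = FALSE) {
  vr <- compute_vr(bundle$diet, period)
  mapped <- unique(bundle$plants$pollen_type)
  cs <- lapply(intersect(vr$included_types, mapped), function(p)
    compute_cr(bundle$cover, bundle$plants, p, bundle$landscape_ids))
  has_cover <- !vapply(cs, `[[`, logical(1L), "zero_cover")
  cs <- cs[has_cover]
  kept <- vapply(cs, `[[`, "", "pollen_type")
  dropped <- setdiff(vr$included_types, kept)
  if (length(dropped) > 0L && !vr_include_unmapped) {
    message("period '", period, "': dropping zero-cover/unmapped pollen ",
            "type(s) and renormalizing vr: ", paste(dropped, collapse = ", "))
  }
  if (length(kept) == 0L) {
    stop("no positive-cover pollen types for period '", period, "'",
         call. = FALSE)
  }
  w <- vr$weights[kept]
  if (!vr_include_unmapped) w <- w / sum(w)
  vr$weights <- w
  vr$included_types <- kept
  list(vr = vr, cover_shares = cs)
}

#' Index table for a bundle
#'
#' Runs the full index computation for each period: diet weights, per-type
#' cover shares, zero-cover handling, and the index itself.
#'
#' @param bundle `fai_bundle`.
#' @param periods Periods to compute (default all of [fai_periods()]).
#' @param vr_include_unmapped Keep the raw diet shares over all listed types
#'   instead of renormalizing over mapped positive-cover types; the mean
#'   index across landscapes then falls below 1 by the unmapped diet
#'   fraction. Default `FALSE`.
#' @return data.frame of class `fai_table`: `landscape_id`, `period`, `fai`.
#' @export
fai_table <- function(bundle, periods = fai_periods(),
                      vr_include_unmapped = FALSE) {
  stopifnot(inherits(bundle, "fai_bundle"))
  n <- length(bundle$landscape_ids)
  rows <- lapply(periods, function(t) {
    pw <- period_weights(bundle, t, vr_include_unmapped)
    fai <- compute_fai(pw$cover_shares, pw$vr, n)
    data.frame(landscape_id = names(fai), period = t, fai = as.numeric(fai),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fai_table", class(out))
  out
}

#' Contribution of pollen types or plant groups to the index
#'
#' The contribution of pollen type `p` to the aggregate index
#' `sum_l fai[l, t]` is exactly `vr[p, t]`, because each type's cover shares
#' sum to 1 across landscapes. A plant group's (e.g. wild vs cultivated, or
#' woody vs herbaceous) contribution is
#' `sum_p vr[p, t] * (group's share of the total mapped cover providing p)`;
#' shares over a partition sum to 1. A set of pollen types gets the sum of
#' their weights.
#'
#' @param bundle `fai_bundle`.
#' @param period One of [fai_periods()].
#' @param grouping `"pollen_type"`, `"origin"`, `"growth_form"`, or a
#'   character vector of pollen types (combined share reported).
#' @param vr_include_unmapped Passed to the weight computation.
#' @return data.frame: `period`, `group_kind`, `group`, `share`.
#' @export
contribution_breakdown <- function(bundle, period, grouping = "origin",
                                   vr_include_unmapped = FALSE) {
  stopifnot(inherits(bundle, "fai_bundle"))
  pw <- period_weights(bundle, period, vr_include_unmapped)
  w <- pw$vr$weights
  types <- names(w)
  if (length(grouping) == 1L && grouping %in% c("origin", "growth_form")) {
    levels <- if (grouping == "origin") c("wild", "cultivated")
              else c("woody", "herbaceous")
    shares <- stats::setNames(numeric(length(levels)), levels)
    for (p in types) {
      spp <- bundle$plants$species[bundle$plants$pollen_type == p]
      sub <- bundle$cover[bundle$cover$species %in% spp, ]
      ann <- bundle$plants[match(sub$species, bundle$plants$species), grouping]
      tot <- sum(sub$cover_m2)
      if (tot <= 0) next
      grp <- tapply(sub$cover_m2, factor(ann, levels = levels), sum, default = 0)
      shares <- shares + w[p] * as.numeric(grp) / tot
    }
    kind <- grouping
    out <- data.frame(period = period, group_kind = kind, group = levels,
                      share = as.numeric(shares) / sum(w),
                      stringsAsFactors = FALSE)
  } else if (length(grouping) == 1L && grouping == "pollen_type") {
    out <- data.frame(period = period, group_kind = "pollen_type",
                      group = types, share = as.numeric(w) / sum(w),
                      stringsAsFactors = FALSE)
  } else {
    grouping <- as.character(grouping)
    unknown <- setdiff(grouping, types)
    if (length(unknown) > 0L) {
      stop("pollen type(s) not in period '", period, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    out <- data.frame(period = period, group_kind = "type_set",
                      group = paste(grouping, collapse = "+"),
                      share = sum(w[grouping]) / sum(w),
                      stringsAsFactors = FALSE)
  }
  out
}
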