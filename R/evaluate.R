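#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`: the intersection of two similarly
#' labeled regions divided by the mean volume of the regions; 0 = disjoint,
#' 1 = identical. Two empty masks are defined to agree perfectly (Dice 1,
#' logged via `message()`), a case real data never produces.
#'
#' @param a,b binary `agetpl_volume`s (or logical/numeric arrays) on the same
#'   grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  am <- if (is_volume(a)) a$data else a
  bm <- if (is_volume(b)) b$data else b
  if (!all(dim(am) == dim(bm))) stop("masks are not on the same grid")
  if (is_volume(a) && is_volume(b)) stopifnot_same_grid(a, b, "masks")
  am <- am > 0; bm <- bm > 0
  na <- sum(am); nb <- sum(bm)
  if (na + nb == 0) {
    message("dice: both masks empty; defined as 1")
    return(1)
  }
  2 * sum(am & bm) / (na + nb)
}

#' Soft Dice on PVE maps
#'
#' Continuous analogue of [dice()] on partial volume estimates:
#' `2 sum(min(a,b)) / (sum(a) + sum(b))`. Provided for inspection; all
#' reported comparisons use hard-label [dice()].
#' @param a,b PVE `agetpl_volume`s on the same grid.
#' @return value in \[0, 1\].
#' @export
soft_dice <- function(a, b) {
  stopifnot_same_grid(a, b)
  sa <- sum(a$data); sb <- sum(b$data)
  if (sa + sb == 0) return(1)
  2 * sum(pmin(a$data, b$data)) / (sa + sb)
}

#' The closed set of segmentation-variant labels
#'
#' The eleven variants compared against the reference segmentation: prior-free
#' ("image"); raw reference priors a priori ("ref-apriori"); image-averaged
#' priors a priori and a posteriori for the young-adult, five-year and
#' ten-year templates; and reference-averaged priors a posteriori for the
#' same three age groups.
#' @return character vector of 11 labels.
#' @export
variant_labels <- function() {
  c("image",
    "ref-apriori",
    paste0("imageavg-apriori-", c("young", "5yr", "10yr")),
    paste0("imageavg-aposteriori-", c("young", "5yr", "10yr")),
    paste0("refavg-aposteriori-", c("young", "5yr", "10yr")))
}

hard_tissue_mask <- function(labels_vol, class) {
  k <- match(class, PVE_CLASSES)
  labels_vol$data == k
}

reference_hard_labels <- function(reference) {
  if (inherits(reference, "agetpl_pve")) classify_hard(reference) else reference
}

#' Run the eleven-variant segmentation comparison for a set of test cases
#'
#' For each case, segments the volume under the closed set of prior
#' configurations ([variant_labels()]), hard-classifies each result, and
#' records the Dice overlap with the case's reference segmentation for GM and
#' WM. Priors are mapped into subject space by registering the subject to the
#' owning template ([warp_priors_to_subject()]); registrations are cached per
#' (case, template).
#'
#' @param test_cases list of cases with `$volume` (or `$brain`), `$mask`,
#'   `$age`, `$reference` (an `agetpl_pve` of ground truth or a hard label
#'   volume), and optionally `$id`.
#' @param prior_library an `agetpl_library` containing five-year and ten-year
#'   entries (with reference-based priors) plus the young-adult entry.
#' @param backend prior-mapping registration backend, `"rigid"` or
#'   `"deformable"`.
#' @param schedule deformable schedule when `backend = "deformable"`.
#' @return data.frame of Dice records: `subject_id`, `tissue`, `config_label`,
#'   `dice`.
#' @export
run_variant_harness <- function(test_cases, prior_library,
                                backend = c("rigid", "deformable"),
                                schedule = c(20, 10, 0)) {
  backend <- match.arg(backend)
  lib <- prior_library$library
  if (is.null(lib$five_year)) stop("prior library is missing the five_year scheme")
  if (is.null(lib$ten_year)) stop("prior library is missing the ten_year scheme")
  young_label <- prior_library$young_adult_label
  fy <- make_age_groups("five_year")
  ty <- make_age_groups("ten_year")
  records <- list()
  for (case in test_cases) {
    vol <- case$volume %||% case$brain
    mask <- case$mask %||% case$brain_mask
    id <- case$id %||% "case"
    ref_labels <- reference_hard_labels(case$reference %||% case$truth_pve)
    g5 <- fy$label[age_group_index(case[["age"]] %||% case$spec$age, fy)]
    g10 <- ty$label[age_group_index(case[["age"]] %||% case$spec$age, ty)]
    need <- list(young = lib$five_year[[young_label]],
                 `5yr` = lib$five_year[[g5]],
                 `10yr` = lib$ten_year[[g10]])
    for (nm in names(need))
      if (is.null(need[[nm]]))
        stop(sprintf("missing prior library entry for %s group of subject %s", nm, id))

    warped <- lapply(need, function(entry) list(
      image = warp_priors_to_subject(entry$priors_image, entry$template, vol,
                                     backend, schedule),
      reference = if (!is.null(entry$priors_reference))
        warp_priors_to_subject(entry$priors_reference, entry$template, vol,
                               backend, schedule)))
    for (nm in names(need))
      if (is.null(warped[[nm]]$reference))
        stop(sprintf("library entry %s lacks reference-based priors", nm))

    run <- function(priors, usage) {
      cfg <- if (is.null(priors)) seg_config() else seg_config(usage)
      p <- if (is.null(priors)) NULL else priors_as_pve(priors)
      classify_hard(segment_em(vol, mask, p, cfg)$pve)
    }
    seg <- list()
    seg[["image"]] <- run(NULL, NULL)
    seg[["ref-apriori"]] <- run(warped$young$image, "a_priori")
    for (nm in c("young", "5yr", "10yr")) {
      seg[[paste0("imageavg-apriori-", nm)]] <- run(warped[[nm]]$image, "a_priori")
      seg[[paste0("imageavg-aposteriori-", nm)]] <- run(warped[[nm]]$image, "a_posteriori")
      seg[[paste0("refavg-aposteriori-", nm)]] <- run(warped[[nm]]$reference, "a_posteriori")
    }
    for (lab in variant_labels())
      for (tis in c("gm", "wm"))
        records[[length(records) + 1L]] <- data.frame(
          subject_id = id, tissue = toupper(tis), config_label = lab,
          dice = dice(hard_tissue_mask(seg[[lab]], tis),
                      hard_tissue_mask(ref_labels, tis)),
          stringsAsFactors = FALSE)
  }
  do.call(rbind, records)
}

#' Subsample a cohort for the age-offset analysis
#'
#' Draws `n_per_group` cases from every five-year age group (the published
#' design uses 4 per group over 14 groups = 56 volumes, two per sex where sex
#' labels exist).
#'
#' @param cases list of cases with ages (`$age` or `$spec$age`).
#' @param n_per_group cases per five-year group.
#' @param seed sampling seed.
#' @return the selected subset of `cases`.
#' @export
sample_offset_cases <- function(cases, n_per_group = 4L, seed = 1L) {
  ages <- vapply(cases, function(x) x[["age"]] %||% x$spec$age, numeric(1))
  fy <- make_age_groups("five_year")
  set.seed(derive_seed(seed, "offset-sample"))
  out <- list()
  for (g in seq_len(nrow(fy))) {
    sel <- which(ages >= fy$low[g] & ages <= fy$high[g])
    if (length(sel) < n_per_group)
      stop(sprintf("age group %s has only %d cases (need %d)",
                   fy$label[g], length(sel), n_per_group))
    sexes <- vapply(cases[sel], function(x) x$sex %||% NA_character_, character(1))
    pick <- if (!anyNA(sexes) && n_per_group %% 2 == 0) {
      c(sample(sel[sexes == "F"], n_per_group / 2),
        sample(sel[sexes == "M"], n_per_group / 2))
    } else sample(sel, n_per_group)
    out <- c(out, cases[pick])
  }
  out
}

#' Age-offset prior analysis
#'
#' For each case, segments with the age-appropriate five-year image-averaged
#' priors applied a posteriori (the proxy standard, offset 0), then with every
#' other five-year group's priors, and records the Dice overlap of each
#' offset segmentation against the offset-0 segmentation per tissue. Offsets
#' are signed five-year steps (-13..13 over 14 groups).
#'
#' @param cases list of cases (see [run_variant_harness()]; no reference
#'   segmentation needed).
#' @param prior_library an `agetpl_library` with all 14 five-year entries.
#' @param backend,schedule prior mapping, as in [run_variant_harness()].
#' @param include_zero include the trivially perfect offset-0 self-comparison
#'   rows (default FALSE).
#' @return data.frame: `subject_id`, `tissue`, `template_offset`, `dice`,
#'   `age_group`.
#' @export
age_offset_analysis <- function(cases, prior_library,
                                backend = c("rigid", "deformable"),
                                schedule = c(20, 10, 0), include_zero = FALSE) {
  backend <- match.arg(backend)
  fy <- make_age_groups("five_year")
  entries <- prior_library$library$five_year
  missing <- setdiff(fy$label, names(entries))
  if (length(missing) > 0)
    stop("missing five-year priors for: ", paste(missing, collapse = ", "))
  records <- list()
  for (case in cases) {
    vol <- case$volume %||% case$brain
    mask <- case$mask %||% case$brain_mask
    id <- case$id %||% "case"
    g0 <- age_group_index(case[["age"]] %||% case$spec$age, fy)
    seg_with <- function(g) {
      entry <- entries[[fy$label[g]]]
      pri <- warp_priors_to_subject(entry$priors_image, entry$template, vol,
                                    backend, schedule)
      classify_hard(segment_em(vol, mask, priors_as_pve(pri),
                               seg_config("a_posteriori"))$pve)
    }
    seg0 <- seg_with(g0)
    for (g in seq_len(nrow(fy))) {
      off <- g - g0
      if (off == 0 && !include_zero) next
      segg <- if (off == 0) seg0 else seg_with(g)
      for (tis in c("gm", "wm"))
        records[[length(records) + 1L]] <- data.frame(
          subject_id = id, tissue = toupper(tis), template_offset = off,
          dice = dice(hard_tissue_mask(segg, tis), hard_tissue_mask(seg0, tis)),
          age_group = fy$label[g0], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, records)
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition with the p-value from the F
#' distribution.
#'
#' @param values numeric observations.
#' @param groups group labels (same length).
#' @return list with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  counts <- table(groups)
  if (any(counts == 0)) stop("group with zero observations: ",
                             paste(names(counts)[counts == 0], collapse = ", "))
  n <- length(values)
  if (n - nlevels(groups) < 2) stop("need at least 2 residual degrees of freedom")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ssb <- sum(counts * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  dfb <- nlevels(groups) - 1L
  dfw <- n - nlevels(groups)
  f <- if (ssw == 0) { if (ssb == 0) 0 else Inf } else (ssb / dfb) / (ssw / dfw)
  list(F = f, df_between = dfb, df_within = dfw,
       p = pf(f, dfb, dfw, lower.tail = FALSE))
}

#' Per-class tissue volumes from a PVE map
#'
#' `volume_k = sum(PVE_k) * voxel volume`, in mm^3, plus GM+WM.
#' @param pve an `agetpl_pve`.
#' @return named vector `c(om, gm, wm, gm_wm)` in mm^3.
#' @export
tissue_volumes <- function(pve) {
  vv <- prod(voxel_size(pve$mask))
  v <- vapply(PVE_CLASSES, function(cl) sum(pve[[cl]]$data) * vv, numeric(1))
  c(v, gm_wm = unname(v[["gm"]] + v[["wm"]]))
}

#' Volumetric aging-trend report
#'
#' Tabulates GM/WM/OM/GM+WM and inner-skull volumes by five-year age group
#' (means and standard errors) and fits the aging trends: a linear model for
#' GM volume over age and a quadratic for WM volume, reporting the GM slope
#' with its 95% CI and the WM vertex age.
#'
#' @param volumes data.frame with columns `age`, `gm`, `wm`, `om`, `gm_wm`,
#'   and optionally `inner_skull` (mm^3).
#' @return list: `table` (per-group means/SEs), `gm_fit`, `wm_fit`,
#'   `gm_slope`, `gm_slope_ci`, `wm_vertex_age`.
#' @export
volumetric_trend_report <- function(volumes) {
  fy <- make_age_groups("five_year")
  gidx <- vapply(volumes$age, age_group_index, integer(1), groups = fy)
  if (anyNA(gidx)) stop("ages outside 20-89")
  volumes$group <- factor(fy$label[gidx], levels = fy$label)
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  cols <- intersect(c("gm", "wm", "om", "gm_wm", "inner_skull"), names(volumes))
  tab <- do.call(rbind, lapply(split(volumes, volumes$group, drop = TRUE), function(d) {
    row <- data.frame(group = d$group[1], n = nrow(d))
    for (cl in cols) {
      row[[paste0(cl, "_mean")]] <- mean(d[[cl]])
      row[[paste0(cl, "_se")]] <- se(d[[cl]])
    }
    row
  }))
  rownames(tab) <- NULL
  gm_fit <- lm(gm ~ age, data = volumes)
  wm_fit <- lm(wm ~ age + I(age^2), data = volumes)
  b <- coef(wm_fit)
  vertex <- if (abs(b[3]) > 0) unname(-b[2] / (2 * b[3])) else NA_real_
  list(table = tab, gm_fit = gm_fit, wm_fit = wm_fit,
       gm_slope = unname(coef(gm_fit)[2]),
       gm_slope_ci = unname(confint(gm_fit)["age", ]),
       wm_vertex_age = vertex)
}

#' Demographics summary by five-year age group
#'
#' @param records data.frame with one row per scan: `age` (years, in
#'   \[20, 89\]), `sex` (`"F"`/`"M"`, optional), `source` (optional).
#' @return data.frame with one row per five-year group plus a `Total` row:
#'   total N, female N, percent female (`round(100 * female / total)`), and
#'   one count column per source.
#' @export
summarize_cohort <- function(records) {
  fy <- make_age_groups("five_year")
  sources <- if ("source" %in% names(records)) sort(unique(records$source)) else character(0)
  if (nrow(records) > 0) {
    gidx <- vapply(records$age, function(a) {
      i <- age_group_index(a, fy)
      if (is.na(i)) stop("record with age outside [20, 89]: ", a)
      i
    }, integer(1))
  } else gidx <- integer(0)
  rows <- lapply(seq_len(nrow(fy)), function(g) {
    d <- records[gidx == g, , drop = FALSE]
    row <- data.frame(age_group = fy$label[g], total = nrow(d),
                      female = if ("sex" %in% names(d)) sum(d$sex == "F") else 0L)
    row$pct_female <- if (row$total > 0) round(100 * row$female / row$total) else 0
    for (s in sources) row[[s]] <- sum(d$source == s)
    row
  })
  tab <- do.call(rbind, rows)
  tot <- data.frame(age_group = "Total", total = sum(tab$total),
                    female = sum(tab$female))
  tot$pct_female <- if (tot$total > 0) round(100 * tot$female / tot$total) else 0
  for (s in sources) tot[[s]] <- sum(tab[[s]])
  rbind(tab, tot)
}

#' Expand printed demographics counts into per-scan records
#'
#' Inverse of [summarize_cohort()] for count tables like the shipped
#' demographics fixture: each row's per-source counts become individual
#' records with the group's lower-bound age and an F/M split matching the
#' female count.
#'
#' @param counts data.frame with `age_group` ("20-24" style), `total`,
#'   `female`, and one column per source.
#' @return data.frame of records (`age`, `sex`, `source`).
#' @export
expand_demographics <- function(counts) {
  meta <- c("age_group", "total", "female", "pct_female")
  sources <- setdiff(names(counts), meta)
  recs <- list()
  for (i in seq_len(nrow(counts))) {
    low <- as.numeric(sub("-.*", "", counts$age_group[i]))
    src <- unlist(lapply(sources, function(s) rep(s, counts[[s]][i])))
    n <- length(src)
    stopifnot(n == counts$total[i])
    sex <- rep("M", n)
    if (counts$female[i] > 0) sex[seq_len(counts$female[i])] <- "F"
    recs[[i]] <- data.frame(age = rep(low, n), sex = sex, source = src,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, recs)
}

#' The shipped demographics fixture (printed five-year count table)
#' @return data.frame of per-group counts by sex and source.
#' @export
demographics_table <- function() {
  read.delim(system.file("extdata", "table1_demographics.tsv", package = "agetpl"),
             stringsAsFactors = FALSE, check.names = FALSE)
}
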