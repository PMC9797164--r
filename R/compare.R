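# Experiment runner: writes/reads phantom cases as plain files and replays
# the four-method comparison (intensity-only and its fiducial/region
# augmentations) on a case. The methods differ ONLY by their weight masks
# over one shared code path, so the comparison isolates the contribution
# of each metric.

.METHOD_WEIGHTS <- list(
  i   = c(fiducial = 0, region = 0, intensity = 100),
  ri  = c(fiducial = 0, region = 1, intensity = 100),
  fi  = c(fiducial = 1, region = 0, intensity = 100),
  fri = c(fiducial = 1, region = 1, intensity = 100))

#' Write a phantom case to a directory of plain files
#'
#' Volumes and masks as MetaImage, landmarks as per-group point-list file
#' pairs, the ground-truth transform as JSON, and a `manifest.json` naming
#' every artifact.
#'
#' @param case an `mmdir_phantom`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vols <- c("moving", "fixed")
  masks <- c("gland_fixed", "gland_moving", "tumor", "tumor_bed",
             "boost_ctv", "body_fixed", "body_moving", "cavity_moving")
  files <- list()
  for (nm in vols) {
    fn <- paste0(nm, ".mha")
    write_metaimage(case[[nm]], file.path(dir, fn))
    files[[nm]] <- fn
  }
  for (nm in masks) {
    fn <- paste0(nm, ".mha")
    write_metaimage(case[[nm]], file.path(dir, fn))
    files[[nm]] <- fn
  }
  write_transform(case$gt_transform, file.path(dir, "gt_transform.json"))
  files$gt_transform <- "gt_transform.json"
  lm <- list()
  for (g in unique(case$landmarks$group)) {
    sel <- case$landmarks$group == g
    ff <- sprintf("landmarks_%s_fixed.txt", g)
    fm <- sprintf("landmarks_%s_moving.txt", g)
    write_point_set(case$landmarks$fixed[sel, , drop = FALSE],
                    file.path(dir, ff))
    write_point_set(case$landmarks$moving[sel, , drop = FALSE],
                    file.path(dir, fm))
    lm[[g]] <- list(fixed = ff, moving = fm)
  }
  manifest <- list(kind = "mmdir_phantom_case", files = files,
                   landmarks = lm,
                   config = unclass(case$config)[
                     setdiff(names(case$config), "levels")],
                   intensity_levels = as.list(case$config$levels))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom case directory
#' @param dir directory written by [write_phantom_case()].
#' @return An `mmdir_phantom`-shaped list.
#' @export
read_phantom_case <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("missing manifest.json in ", dir)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  need <- function(nm, as_mask = FALSE) {
    fn <- man$files[[nm]]
    if (is.null(fn)) stop("manifest missing artifact '", nm, "'")
    fp <- file.path(dir, fn)
    if (!file.exists(fp)) stop("missing case artifact '", nm, "' (", fn, ")")
    read_volume(fp, as_mask = as_mask)
  }
  vols <- list(moving = need("moving"), fixed = need("fixed"))
  masks <- c("gland_fixed", "gland_moving", "tumor", "tumor_bed",
             "boost_ctv", "body_fixed", "body_moving", "cavity_moving")
  for (nm in masks) vols[[nm]] <- need(nm, as_mask = TRUE)
  vols$gt_transform <- read_transform(file.path(dir,
                                                man$files$gt_transform))
  pf <- list(); pm <- list(); gr <- character(0)
  for (g in names(man$landmarks)) {
    a <- read_point_set(file.path(dir, man$landmarks[[g]]$fixed))
    b <- read_point_set(file.path(dir, man$landmarks[[g]]$moving))
    pf[[g]] <- a; pm[[g]] <- b; gr <- c(gr, rep(g, nrow(a)))
  }
  vols$landmarks <- paired_points(do.call(rbind, pf), do.call(rbind, pm),
                                  gr)
  vols$config <- man$config
  structure(vols, class = "mmdir_phantom")
}

#' Replay the multi-metric method comparison on a phantom case
#'
#' Runs each requested method — `i` (intensity only), `ri` (+region),
#' `fi` (+fiducial), `fri` (all three) — as a weight mask over the single
#' registration code path, and reports per-method target registration
#' error by tissue group plus Dice/Hausdorff of the deformed tumor+2 vs
#' the tumor bed and the deformed tumor+3 vs the boost-CTV. Fiducial
#' pairs for the objective are extracted automatically (Harris corners in
#' the unaffected fixed gland, paired by correlation search) and shared by
#' all methods; they are distinct from the held-out ground-truth landmarks
#' used for TRE. Deterministic given `seed`.
#'
#' @param case an `mmdir_phantom` or a case directory path.
#' @param methods subset of `c("i", "ri", "fi", "fri")`.
#' @param cfg an [registration_config()] (its weights are overridden per
#'   method).
#' @param seed integer seed for the whole comparison.
#' @param n_corners corners requested for the fiducial objective.
#' @param search_radius_mm,patch_radius_mm,min_corr see [match_points()].
#' @return An object of class `mmdir_comparison`: a data.frame (one row
#'   per method) with attributes `registrations`, `pairs`, `seed`.
#' @export
run_method_comparison <- function(case, methods = c("i", "ri", "fi", "fri"),
                                  cfg = registration_config(), seed = 1,
                                  n_corners = 60, search_radius_mm = 22,
                                  patch_radius_mm = 8, min_corr = 0.5) {
  if (is.character(case)) case <- read_phantom_case(case)
  methods <- match.arg(methods, names(.METHOD_WEIGHTS), several.ok = TRUE)
  tumor2 <- expand_margin(case$tumor, 20, limit = case$body_moving)
  tumor3 <- expand_margin(case$tumor, 30, limit = case$body_moving)

  needs_pairs <- any(vapply(methods,
                            function(m) .METHOD_WEIGHTS[[m]]["fiducial"] > 0,
                            TRUE))
  pairs <- NULL
  if (needs_pairs) {
    corners <- harris_corners_3d(case$fixed, mask = case$gland_fixed,
                                 n_points = n_corners)
    if (nrow(corners) == 0) stop("no corners found in the fixed gland")
    pairs <- match_points(case$fixed, case$moving, corners,
                          search_radius_mm = search_radius_mm,
                          patch_radius_mm = patch_radius_mm,
                          min_corr = min_corr)
  }

  # the affine stage is intensity-only and shared by all methods
  cfg_a <- cfg
  cfg_a$seed <- as.integer(seed)
  affine <- if (cfg$do_affine)
    register_affine(case$fixed, case$moving, cfg_a)
  else affine_transform()

  rows <- list(); regs <- list()
  for (m in methods) {
    cfg_m <- cfg
    cfg_m$weights <- do.call(metric_weights,
                             as.list(.METHOD_WEIGHTS[[m]]))
    cfg_m$seed <- as.integer(seed)
    reg <- register_multimetric(case$fixed, case$moving, cfg_m,
                                pairs = pairs,
                                roi_fixed = case$gland_fixed,
                                roi_moving = case$gland_moving,
                                fixed_mask = case$body_fixed,
                                affine = affine)
    tr <- reg$transform
    tre <- target_registration_error(case$landmarks, tr)
    g <- tre$groups
    gv <- function(grp, col) {
      i <- match(grp, g$group)
      if (is.na(i)) NA_real_ else g[[col]][i]
    }
    t2d <- propagate_mask(tumor2, tr, case$fixed)
    t3d <- propagate_mask(tumor3, tr, case$fixed)
    rows[[m]] <- data.frame(
      method = m,
      tre_soft = gv("soft_tissue", "mean"),
      tre_soft_sd = gv("soft_tissue", "sd"),
      tre_rigid = gv("rigid", "mean"),
      tre_rigid_sd = gv("rigid", "sd"),
      tre_boundary = gv("boundary", "mean"),
      tre_boundary_sd = gv("boundary", "sd"),
      dsc_t2_bed = dice(t2d, case$tumor_bed),
      hd_t2_bed = hausdorff(t2d, case$tumor_bed),
      dsc_t3_ctv = dice(t3d, case$boost_ctv),
      hd_t3_ctv = hausdorff(t3d, case$boost_ctv),
      stringsAsFactors = FALSE)
    regs[[m]] <- reg
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("mmdir_comparison", "data.frame"),
            registrations = regs, pairs = pairs, seed = seed)
}

#' @export
print.mmdir_comparison <- function(x, ...) {
  cat("<mmdir_comparison> TRE (mm) by group and contour overlap\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a comparison report as CSV
#' @param report an `mmdir_comparison`.
#' @param path output `.csv`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

# ------------------------------------------------------------ config file

# Parse a flat "key: value" text file (or JSON object) into a named list.
.parse_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  first <- trimws(lines[nzchar(trimws(lines))])[1]
  if (!is.na(first) && startsWith(first, "{"))
    return(jsonlite::read_json(path, simplifyVector = TRUE))
  out <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: '", ln, "'")
    val <- trimws(m[3])
    parts <- strsplit(val, "[,[:space:]]+")[[1]]
    suppressWarnings(num <- as.numeric(parts))
    out[[m[2]]] <- if (!anyNA(num)) num
      else if (length(parts) == 1 && tolower(parts) %in% c("true", "false"))
        tolower(parts) == "true"
      else val
  }
  out
}

#' Load and validate a configuration file
#'
#' Flat `key: value` text (or a JSON object). Unknown keys are rejected
#' with an error naming them; all defaults are materialized so the
#' returned object fully documents the run. Nested settings use dotted
#' keys (`weights.fiducial`, `mi.n_bins`, `levels.gland`); the bare metric
#' names `fiducial`, `region`, `intensity` are accepted as weight
#' shorthands.
#'
#' @param path config file; an empty file yields the full default config.
#' @param kind `"registration"` or `"phantom"`.
#' @return An [registration_config()] or [phantom_config()] object.
#' @export
load_config <- function(path, kind = c("registration", "phantom")) {
  kind <- match.arg(kind)
  vals <- .parse_config_file(path)
  if (kind == "registration") {
    plain <- setdiff(names(formals(registration_config)),
                     c("weights", "mi"))
    wkeys <- names(formals(metric_weights))
    mkeys <- setdiff(names(formals(mi_config)),
                     c("fixed_range", "moving_range"))
    known <- c(plain, wkeys, paste0("weights.", wkeys),
               paste0("mi.", mkeys))
    bad <- setdiff(names(vals), known)
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    wargs <- list(); margs <- list(); args <- list()
    for (k in names(vals)) {
      if (k %in% plain) args[[k]] <- vals[[k]]
      else if (k %in% wkeys) wargs[[k]] <- vals[[k]]
      else if (startsWith(k, "weights."))
        wargs[[sub("^weights\\.", "", k)]] <- vals[[k]]
      else margs[[sub("^mi\\.", "", k)]] <- vals[[k]]
    }
    if (length(wargs)) args$weights <- do.call(metric_weights, wargs)
    if (length(margs)) args$mi <- do.call(mi_config, margs)
    do.call(registration_config, args)
  } else {
    plain <- setdiff(names(formals(phantom_config)), "levels")
    lv <- eval(formals(phantom_config)$levels)
    known <- c(plain, paste0("levels.", names(lv)))
    bad <- setdiff(names(vals), known)
    if (length(bad))
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    args <- list()
    for (k in names(vals)) {
      if (k %in% plain) args[[k]] <- vals[[k]]
      else lv[[sub("^levels\\.", "", k)]] <- vals[[k]]
    }
    args$levels <- lv
    do.call(phantom_config, args)
  }
}
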