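## Synthetic oocyte phantoms: ellipse-composed cells with class-conditional
## region masks (GV only in PI; FPB/FFPB only in MII), blur, noise and
## brightness variation, so the whole pipeline is trainable without
## clinical data.

#' Maturity class labels
#' @return character vector `c("MI", "MII", "PI")`.
#' @export
maturity_classes <- function() c("MI", "MII", "PI")

#' Canonical input channel names, in tensor order
#'
#' Channel 1 is the grayscale oocyte image; channels 2-15 are binary
#' region masks.
#'
#' @return character vector of 15 channel names.
#' @export
canonical_channels <- function() c(
  "oocyte_image", "clear_cytoplasm", "diffuse_cytoplasmic_granularity",
  "cytoplasmic_granular_area", "ser_cluster", "vacuoles", "dark_cytoplasm",
  "first_polar_body", "multi_polar_body", "fragmented_first_polar_body",
  "second_polar_body", "perivitelline_space", "zona_pellucida",
  "germinal_vesicle", "cumulus_corona_cells")

#' Canonical region (mask) names
#' @return the 14 mask channel names (all canonical channels except the image).
#' @export
canonical_regions <- function() canonical_channels()[-1]

#' Phantom generator parameters
#'
#' Geometry is expressed as fractions of the oocyte radius so phantoms
#' scale with `side`. GV and FPB area fractions default to the reported
#' proportions of the oocyte surface (11 % and 12 %).
#'
#' @param side image side length in pixels.
#' @param oocyte_radius_frac range (length 2) of the oocyte outer radius as a
#'   fraction of `side`; records emulate per-oocyte crops, so the cell
#'   fills most of the frame.
#' @param zp_thickness_frac zona pellucida thickness as a fraction of the
#'   oocyte radius.
#' @param cytoplasm_frac cytoplasm (oolemma) radius as a fraction of the
#'   oocyte radius.
#' @param gv_area_frac range of the GV area as a fraction of the oocyte area.
#' @param fpb_area_frac range of the FPB (+FFPB) area as a fraction of the
#'   oocyte area.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param noise_sd additive Gaussian intensity noise (0-255 scale).
#' @param brightness_jitter multiplicative brightness jitter half-range
#'   (fraction).
#' @param frag_prob probability that an MII phantom carries a fragmented
#'   first polar body instead of a single one.
#' @param clutter_prob probability of each incidental, class-independent
#'   region (vacuoles, granularity, dark cytoplasm, ...).
#' @return validated list of class `phantom_params`.
#' @export
phantom_params <- function(side = 256L,
                           oocyte_radius_frac = c(0.36, 0.42),
                           zp_thickness_frac = 0.12,
                           cytoplasm_frac = 0.70,
                           gv_area_frac = c(0.095, 0.125),
                           fpb_area_frac = c(0.105, 0.135),
                           blur_sigma = 1.5,
                           noise_sd = 6,
                           brightness_jitter = 0.10,
                           frag_prob = 0.15,
                           clutter_prob = 0.25) {
  p <- list(side = as.integer(side), oocyte_radius_frac = oocyte_radius_frac,
            zp_thickness_frac = zp_thickness_frac, cytoplasm_frac = cytoplasm_frac,
            gv_area_frac = gv_area_frac, fpb_area_frac = fpb_area_frac,
            blur_sigma = blur_sigma, noise_sd = noise_sd,
            brightness_jitter = brightness_jitter, frag_prob = frag_prob,
            clutter_prob = clutter_prob)
  if (p$side < 32) stop("side must be >= 32 px")
  if (any(p$oocyte_radius_frac <= 0) || any(p$gv_area_frac <= 0) || any(p$fpb_area_frac <= 0))
    stop("all radii/area fractions must be positive")
  if (max(p$gv_area_frac) >= p$cytoplasm_frac^2)
    stop("GV must fit inside the cytoplasm")
  for (nm in c("frag_prob", "clutter_prob"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must be in [0, 1]")
  if (p$noise_sd < 0 || p$blur_sigma < 0 || p$brightness_jitter < 0)
    stop("noise_sd, blur_sigma and brightness_jitter must be non-negative")
  class(p) <- "phantom_params"
  p
}

new_oocyte_record <- function(id, image, masks, label) {
  structure(list(id = id, image = image, masks = masks, label = label),
            class = "oocyte_record")
}

#' @export
print.oocyte_record <- function(x, ...) {
  nz <- names(x$masks)[vapply(x$masks, function(m) any(m > 0), logical(1))]
  cat("<oocyte_record> id=", x$id, " label=", x$label,
      " size=", nrow(x$image), "x", ncol(x$image),
      "\n  nonempty regions: ", paste(nz, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate an oocyte record's invariants
#'
#' Checks mask geometry, binarity and the class-conditional presence rules
#' (PI implies GV and no FPB/FFPB; MII implies FPB or FFPB and no GV; MI
#' implies neither).
#'
#' @param record an `oocyte_record`.
#' @return `record`, invisibly; errors on violation.
#' @export
validate_record <- function(record) {
  stopifnot(inherits(record, "oocyte_record"))
  if (!record$label %in% maturity_classes())
    stop("unknown label '", record$label, "'; admissible: ",
         paste(maturity_classes(), collapse = ", "))
  d <- dim(record$image)
  miss <- setdiff(canonical_regions(), names(record$masks))
  if (length(miss)) stop("missing masks: ", paste(miss, collapse = ", "))
  for (nm in canonical_regions()) {
    m <- record$masks[[nm]]
    if (!identical(dim(m), d)) stop("mask '", nm, "' shape differs from image")
    if (!all(m %in% c(0, 1))) stop("mask '", nm, "' is not binary")
  }
  gv <- sum(record$masks$germinal_vesicle)
  fpb <- sum(record$masks$first_polar_body) + sum(record$masks$fragmented_first_polar_body)
  ok <- switch(record$label,
    PI  = gv >= 1 && fpb == 0,
    MII = fpb >= 1 && gv == 0,
    MI  = gv == 0 && fpb == 0)
  if (!ok) stop("record ", record$id, " violates the ", record$label,
                " mask-presence rule (GV px = ", gv, ", FPB px = ", fpb, ")")
  invisible(record)
}

## One random blob (small ellipse) constrained to `allowed`.
random_blob <- function(side, allowed, r_range) {
  pts <- which(allowed, arr.ind = TRUE)
  if (nrow(pts) == 0) return(matrix(FALSE, side, side))
  ctr <- pts[sample.int(nrow(pts), 1), ]
  r <- stats::runif(1, r_range[1], r_range[2])
  ellipse_mask(side, ctr[1], ctr[2], r, r * stats::runif(1, 0.7, 1.3),
               stats::runif(1, 0, pi)) & allowed
}

#' Generate one synthetic oocyte phantom
#'
#' Draws a concentric-ellipse cell (cytoplasm inside a zona pellucida
#' annulus, with the perivitelline space between) and class-conditional
#' structures: a germinal vesicle disc for PI, a first polar body (possibly
#' fragmented into several discs) for MII, neither for MI. Incidental
#' class-independent regions (granularity, vacuoles, dark cytoplasm, ...)
#' are added with probability `params$clutter_prob`. The rendered image
#' gets brightness jitter, Gaussian blur and additive noise, then is
#' quantized to 8-bit.
#'
#' @param label one of `"MI"`, `"MII"`, `"PI"`.
#' @param params a [phantom_params()] object.
#' @param seed non-negative integer; identical `(label, params, seed)`
#'   yields an identical record.
#' @param id record identifier (default derived from label and seed).
#' @return an `oocyte_record` satisfying [validate_record()].
#' @export
generate_phantom <- function(label, params = phantom_params(), seed = 0L,
                             id = sprintf("%s_s%d", label, as.integer(seed))) {
  if (!label %in% maturity_classes())
    stop("unknown label '", label, "'; admissible: ",
         paste(maturity_classes(), collapse = ", "))
  stopifnot(inherits(params, "phantom_params"))
  side <- params$side
  with_seed(seed, {
    R <- stats::runif(1, params$oocyte_radius_frac[1], params$oocyte_radius_frac[2]) * side
    slack <- max(side / 2 - 1.18 * R - 2, 0)   # keep the halo inside the frame
    cy <- side / 2 + stats::runif(1, -slack, slack)
    cx <- side / 2 + stats::runif(1, -slack, slack)
    ratio <- stats::runif(1, 0.90, 1.0)
    phi <- stats::runif(1, 0, pi)

    oo <- ellipse_mask(side, cy, cx, R, R * ratio, phi)          # oocyte support
    zp_in <- ellipse_mask(side, cy, cx, R * (1 - params$zp_thickness_frac),
                          R * ratio * (1 - params$zp_thickness_frac), phi)
    cyt <- ellipse_mask(side, cy, cx, R * params$cytoplasm_frac,
                        R * ratio * params$cytoplasm_frac, phi)
    zp <- oo & !zp_in
    pvs <- zp_in & !cyt

    area_oo <- sum(oo)
    empty <- matrix(FALSE, side, side)
    masks <- stats::setNames(rep(list(empty), length(canonical_regions())),
                             canonical_regions())
    masks$zona_pellucida <- zp
    masks$perivitelline_space <- pvs

    ## class-conditional structures
    if (label == "PI") {
      frac <- stats::runif(1, params$gv_area_frac[1], params$gv_area_frac[2])
      r_gv <- sqrt(frac * area_oo / pi)
      rmax <- R * params$cytoplasm_frac * ratio - r_gv - 1
      d <- stats::runif(1, 0, max(rmax, 0))
      a <- stats::runif(1, 0, 2 * pi)
      masks$germinal_vesicle <- ellipse_mask(side, cy + d * sin(a), cx + d * cos(a),
                                             r_gv, r_gv) & cyt
    } else if (label == "MII") {
      frac <- stats::runif(1, params$fpb_area_frac[1], params$fpb_area_frac[2])
      total <- frac * area_oo
      frag <- stats::runif(1) < params$frag_prob
      k <- if (frag) sample(2:4, 1) else 1L
      shares <- stats::runif(k, 0.6, 1.4); shares <- shares / sum(shares)
      a0 <- stats::runif(1, 0, 2 * pi)
      rin_min <- R * (1 - params$zp_thickness_frac) * ratio
      fmask <- empty
      for (i in seq_len(k)) {
        r_f <- sqrt(shares[i] * total / pi)
        d <- max(rin_min - r_f - 1, 0)
        a <- a0 + (i - (k + 1) / 2) * 0.45 + stats::runif(1, -0.08, 0.08)
        fmask <- fmask | (ellipse_mask(side, cy + d * sin(a), cx + d * cos(a),
                                       r_f, r_f) & zp_in)
      }
      if (frag) masks$fragmented_first_polar_body <- fmask
      else masks$first_polar_body <- fmask
    }

    ## incidental, class-independent clutter (sized relative to the cell)
    p <- params$clutter_prob
    blob_r <- c(0.08, 0.20) * R
    if (stats::runif(1) < p)
      masks$diffuse_cytoplasmic_granularity <- random_blob(side, cyt, blob_r)
    if (stats::runif(1) < p)
      masks$cytoplasmic_granular_area <- random_blob(side, cyt, blob_r)
    if (stats::runif(1) < p * 0.6)
      masks$ser_cluster <- random_blob(side, cyt, blob_r * 0.7)
    if (stats::runif(1) < min(1, 3.2 * p)) {
      v <- empty
      for (i in seq_len(sample(2:4, 1))) v <- v | random_blob(side, cyt, blob_r * 0.5)
      masks$vacuoles <- v
    }
    ## bright refractile inclusions: image-only distractors with no mask
    ## channel of their own, present in every class
    refractile <- empty
    if (stats::runif(1) < min(1, 3.2 * p))
      for (i in seq_len(sample(1:3, 1)))
        refractile <- refractile | random_blob(side, cyt, blob_r * 0.45)
    if (stats::runif(1) < p)
      masks$dark_cytoplasm <- random_blob(side, cyt, blob_r)
    if (stats::runif(1) < p * 0.4)
      masks$multi_polar_body <- random_blob(side, pvs, blob_r * 0.5)
    if (stats::runif(1) < p * 0.25)
      masks$second_polar_body <- random_blob(side, pvs, blob_r * 0.5)
    if (stats::runif(1) < p) {
      halo <- ellipse_mask(side, cy, cx, R * 1.12, R * ratio * 1.12, phi) & !oo
      masks$cumulus_corona_cells <- random_blob(side, halo, blob_r)
    }

    fpb_all <- masks$first_polar_body | masks$fragmented_first_polar_body
    gv <- masks$germinal_vesicle
    ## structural masks are class-unconditional: they may overlap the GV
    ## and FPB discs, so no class signal leaks into them
    masks$clear_cytoplasm <- cyt &
      !masks$diffuse_cytoplasmic_granularity & !masks$cytoplasmic_granular_area &
      !masks$ser_cluster & !masks$vacuoles & !masks$dark_cytoplasm

    ## render intensities
    ## intensity layering: the GV disc is dark and the FPB disc bright,
    ## but vacuoles share the GV intensity and refractile inclusions the
    ## FPB intensity in every class, so single pixels are ambiguous and
    ## only region scale/context separates the classes in the raw image
    img <- matrix(35, side, side)
    img[zp] <- 155
    img[masks$perivitelline_space] <- 80
    img[cyt] <- 115
    img[masks$diffuse_cytoplasmic_granularity] <- 105
    img[masks$cytoplasmic_granular_area] <- 100
    img[masks$ser_cluster] <- 108
    img[masks$dark_cytoplasm] <- 92
    img[masks$cumulus_corona_cells] <- 90
    ## correlated cytoplasmic texture: darkish and brightish patches of
    ## many scales occur in every class, so patch presence alone carries
    ## no class signal — landmarks are the uniform, sharply bounded
    ## discs repainted below
    tex <- EBImage::imageData(EBImage::gblur(
      EBImage::Image(matrix(stats::rnorm(side * side), side, side)),
      sigma = max(1, 0.10 * R)))
    tex <- tex / max(stats::sd(tex), 1e-8)
    img[cyt] <- pmin(150, pmax(55, img[cyt] + 28 * tex[cyt]))
    img[masks$vacuoles] <- 58
    img[refractile] <- 195
    img[gv] <- 58
    img[fpb_all] <- 195
    img <- img * (1 + stats::runif(1, -params$brightness_jitter, params$brightness_jitter))
    if (params$blur_sigma > 0)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = params$blur_sigma))
    if (params$noise_sd > 0)
      img <- img + matrix(stats::rnorm(side * side, sd = params$noise_sd), side, side)
    img <- matrix(pmin(255, pmax(0, round(img))), side, side)

    rec <- new_oocyte_record(id, img,
                             lapply(masks, function(m) m * 1), label)
    validate_record(rec)
  })
}

#' Generate a labeled phantom dataset
#'
#' @param counts named integer vector / list mapping class to record count,
#'   e.g. `c(MI = 44, MII = 663, PI = 59)`.
#' @param params a [phantom_params()] object.
#' @param seed integer; the whole dataset is deterministic in it.
#' @return list with `records` (list of `oocyte_record`) and `manifest`
#'   (data.frame with columns `id`, `label`).
#' @export
generate_dataset <- function(counts, params = phantom_params(), seed = 0L) {
  counts <- unlist(counts)
  bad <- setdiff(names(counts), maturity_classes())
  if (length(bad)) stop("unknown classes in counts: ", paste(bad, collapse = ", "))
  if (any(counts < 0)) stop("counts must be non-negative")
  records <- list()
  rows <- list()
  k <- 0L
  for (cls in maturity_classes()) {
    n <- if (cls %in% names(counts)) counts[[cls]] else 0L
    if (is.na(n)) n <- 0L
    for (i in seq_len(n)) {
      k <- k + 1L
      id <- sprintf("%s_%04d", cls, i)
      rec <- generate_phantom(cls, params, seed = derive_seed(seed, k), id = id)
      records[[id]] <- rec
      rows[[k]] <- data.frame(id = id, label = cls, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (k > 0) do.call(rbind, rows)
              else data.frame(id = character(), label = character())
  list(records = records, manifest = manifest)
}

#' Write a phantom dataset to disk
#'
#' One 8-bit grayscale PNG per record, one binary PNG per nonempty region
#' (`<id>_<region>.png`) and a `manifest.csv` with `id`, `label`,
#' `image_path` and one mask-path column per canonical region (empty when
#' the region is absent).
#'
#' @param records list of `oocyte_record`.
#' @param directory output directory (created if needed).
#' @return path to the written manifest, invisibly.
#' @export
write_dataset <- function(records, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory ", directory)
  regions <- canonical_regions()
  rows <- lapply(records, function(rec) {
    img_path <- file.path(directory, paste0(rec$id, ".png"))
    png::writePNG(rec$image / 255, img_path)
    row <- list(id = rec$id, label = rec$label, image_path = basename(img_path))
    for (nm in regions) {
      col <- paste0("mask_", nm)
      if (any(rec$masks[[nm]] > 0)) {
        mp <- file.path(directory, paste0(rec$id, "_", nm, ".png"))
        png::writePNG(rec$masks[[nm]], mp)
        row[[col]] <- basename(mp)
      } else row[[col]] <- ""
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else {
    cols <- c("id", "label", "image_path", paste0("mask_", regions))
    as.data.frame(stats::setNames(rep(list(character()), length(cols)), cols))
  }
  path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' Absent mask files are restored as all-zero masks.
#'
#' @param directory dataset directory containing `manifest.csv`.
#' @return list with `records` and `manifest` as in [generate_dataset()].
#' @export
read_dataset <- function(directory) {
  path <- file.path(directory, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv under ", directory)
  manifest <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  records <- list()
  for (r in seq_len(nrow(manifest))) {
    img <- round(png::readPNG(file.path(directory, manifest$image_path[r])) * 255)
    masks <- list()
    for (nm in canonical_regions()) {
      mp <- manifest[[paste0("mask_", nm)]][r]
      masks[[nm]] <- if (!is.na(mp) && nzchar(mp))
        binarize(png::readPNG(file.path(directory, mp)))
      else matrix(0, nrow(img), ncol(img))
    }
    rec <- new_oocyte_record(manifest$id[r], img, masks, manifest$label[r])
    records[[rec$id]] <- validate_record(rec)
  }
  list(records = records, manifest = manifest[, c("id", "label")])
}
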