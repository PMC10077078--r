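#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic radiograph-like cohort: number of
#' images, 3-class label priors (satisfactory / malpositioned / bronchial
#' tube position), radiography-system ("manufacturer") intensity offsets,
#' department names, the patient age distribution, the target strength of
#' the label-manufacturer association, pixel noise, and the rendered image
#' side. All randomness downstream flows from `seed` through documented
#' per-stage / per-record sub-seeds, so any single artifact can be
#' regenerated in isolation.
#'
#' Default priors (0.579, 0.353, 0.068) follow the class balance of a
#' 7081-image NGT cohort (4100 satisfactory, 2500 malpositioned, 481
#' bronchial). The default `label_tag_r2` of 0.07 plants only a weak
#' association between acquisition metadata and the class label, the regime
#' reported for real cohorts. Intensity offsets between radiography systems
#' are a modeling choice (real inter-system pixel differences are not
#' characterized); defaults are large enough to be visible above noise.
#'
#' @param n_images number of records to generate (>= 0).
#' @param class_priors named numeric vector of 3 probabilities summing to 1,
#'   in the order satisfactory, malpositioned, bronchial.
#' @param manufacturer_levels named numeric vector: names are system names,
#'   values are additive intensity offsets in 16-bit gray levels.
#' @param department_levels character vector of department names.
#' @param age_distribution numeric `c(mean, sd)` of patient age in years
#'   (truncated below at 0).
#' @param label_tag_r2 target fraction in [0, 1] of label variance explained
#'   by the manufacturer tag (association planted by conditional sampling).
#' @param noise_sd additive Gaussian pixel noise, in gray levels (>= 0).
#' @param image_size rendered image side in pixels.
#' @param seed master integer seed.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_images = 1000,
                         class_priors = c(satisfactory = 0.579,
                                          malpositioned = 0.353,
                                          bronchial = 0.068),
                         manufacturer_levels = c(system_a = 0,
                                                 system_b = 1500,
                                                 system_c = 3000),
                         department_levels = c("general_wards",
                                               "intensive_care",
                                               "accident_emergency"),
                         age_distribution = c(mean = 67, sd = 16),
                         label_tag_r2 = 0.07,
                         noise_sd = 800,
                         image_size = 64,
                         seed = 1) {
  if (length(class_priors) != 3L || any(class_priors < 0)) {
    stop2("class_priors must be 3 non-negative probabilities")
  }
  if (abs(sum(class_priors) - 1) > 1e-9) {
    stop2("class_priors must sum to 1 (within 1e-9); got ", sum(class_priors))
  }
  if (n_images < 0) stop2("n_images must be >= 0")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  if (label_tag_r2 < 0 || label_tag_r2 > 1) stop2("label_tag_r2 must be in [0, 1]")
  if (is.null(names(class_priors))) {
    names(class_priors) <- ngt_classes()
  }
  structure(list(
    n_images = as.integer(n_images),
    class_priors = class_priors,
    manufacturer_levels = manufacturer_levels,
    department_levels = department_levels,
    age_distribution = age_distribution,
    label_tag_r2 = label_tag_r2,
    noise_sd = noise_sd,
    image_size = as.integer(image_size),
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' The three tube-position classes
#' @return character vector `c("satisfactory", "malpositioned", "bronchial")`.
#' @export
ngt_classes <- function() c("satisfactory", "malpositioned", "bronchial")

# Mixing weight w such that sampling manufacturer = class-linked system with
# probability w (uniform otherwise) yields a population pooled R^2 (one-hot
# label regressed on one-hot manufacturer) equal to `target`.
# With priors p_c and M systems, P(m | c) = w [m = m_c] + (1 - w) / M.
calibrate_mix_weight <- function(priors, n_manuf, target) {
  pooled_r2 <- function(w) {
    C <- length(priors)
    m_of <- ((seq_len(C) - 1L) %% n_manuf) + 1L  # class -> linked system
    joint <- matrix(0, C, n_manuf)
    for (c in seq_len(C)) {
      joint[c, ] <- priors[c] * (1 - w) / n_manuf
      joint[c, m_of[c]] <- joint[c, m_of[c]] + priors[c] * w
    }
    qm <- colSums(joint)
    sst <- sum(priors * (1 - priors))
    sse_explained <- 0
    for (c in seq_len(C)) {
      pc_given_m <- ifelse(qm > 0, joint[c, ] / qm, 0)
      sse_explained <- sse_explained + sum(qm * (pc_given_m - priors[c])^2)
    }
    sse_explained / sst
  }
  if (target <= 0) return(0)
  if (sum(priors * (1 - priors)) == 0) return(0)  # degenerate label: no association possible
  if (pooled_r2(1) <= target) {
    warning("requested label_tag_r2 exceeds the maximum attainable; using full mixing")
    return(1)
  }
  stats::uniroot(function(w) pooled_r2(w) - target, c(0, 1), tol = 1e-9)$root
}

#' Generate a synthetic cohort manifest
#'
#' Draws `n_images` study records: 3-class tube-position label from the
#' configured priors, patient identifiers (patients contribute 1-3 studies
#' each), sex (M:F about 1.45:1), view (AP-heavy), source image dimensions,
#' manufacturer sampled conditionally on the label so that the
#' label-manufacturer association matches `label_tag_r2`, department, ISO-8601
#' study and birth dates (age drawn from the configured normal, truncated at
#' 0 -- a small pediatric tail is intentional so the quality-control filter
#' has work to do), a short report text carrying tube keywords, and three
#' simulated rater labels (each rater reproduces the true label with
#' probability 0.9).
#'
#' @param config a [synth_config()].
#' @return a `data.frame` with one row per record (the cohort manifest).
#' @export
generate_manifest <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_images
  cls <- ngt_classes()
  cols <- c("record_id", "patient_id", "study_date", "birth_date", "sex",
            "view", "body_part", "width", "height", "manufacturer",
            "department", "report_text", "label", "rater1", "rater2", "rater3")
  if (n == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    out$width <- integer(0); out$height <- integer(0)
    return(out)
  }
  with_seed(config$seed, "manifest", {
    label <- sample(cls, n, replace = TRUE, prob = config$class_priors)

    # patients: 1-3 studies each, patient-level sex and birth date
    n_pat <- max(1L, ceiling(n / 1.3))
    pat_of <- sort(sample.int(n_pat, n, replace = TRUE))
    pat_ids <- sprintf("pat%05d", pat_of)
    pat_sex <- sample(c("M", "F"), n_pat, replace = TRUE, prob = c(0.59, 0.41))
    ages_y <- pmax(0, stats::rnorm(n_pat, config$age_distribution[["mean"]],
                                   config$age_distribution[["sd"]]))

    study_date <- as.Date("2007-06-01") +
      sample.int(as.integer(as.Date("2019-08-31") - as.Date("2007-06-01")), n,
                 replace = TRUE)
    birth_pat <- as.Date("2019-08-31") - round(ages_y * 365.25)
    birth_date <- birth_pat[pat_of]
    birth_date <- pmin(birth_date, study_date)  # never born after the study

    # manufacturer conditionally on class to plant the weak association
    manu <- names(config$manufacturer_levels)
    w <- calibrate_mix_weight(config$class_priors, length(manu),
                              config$label_tag_r2)
    linked <- manu[((match(label, cls) - 1L) %% length(manu)) + 1L]
    use_link <- stats::runif(n) < w
    manufacturer <- ifelse(use_link, linked,
                           sample(manu, n, replace = TRUE))

    department <- sample(config$department_levels, n, replace = TRUE)
    view <- sample(c("AP", "PA"), n, replace = TRUE, prob = c(0.7, 0.3))
    width <- sample(c(900L, 1024L, 2500L, 3056L, 3520L, 4280L), n,
                    replace = TRUE, prob = c(0.02, 0.08, 0.3, 0.3, 0.2, 0.1))
    height <- sample(c(902L, 1024L, 2048L, 2544L, 3056L), n,
                     replace = TRUE, prob = c(0.02, 0.08, 0.3, 0.4, 0.2))

    templates <- c(
      satisfactory = "Nasogastric tube in situ. Tip projected below the diaphragm within the stomach. Satisfactory placement, safe to feed.",
      malpositioned = "NG tube placement suboptimal. Tip within the distal oesophagus; advise advancement and repeat film before feeding. Insertion to be reviewed.",
      bronchial = "The tube deviates at the carina and follows the right main bronchus. Immediate removal advised."
    )
    report_text <- unname(templates[label])
    plain <- stats::runif(n) < 0.03   # a few reports without tube keywords
    report_text[plain] <- "Clear lungs. No acute cardiopulmonary abnormality."

    # three raters, each correct with probability 0.9
    rate <- function() {
      ok <- stats::runif(n) < 0.9
      wrong <- vapply(label, function(l) sample(setdiff(cls, l), 1L), "")
      ifelse(ok, label, wrong)
    }
    out <- data.frame(
      record_id = sprintf("img%06d", seq_len(n)),
      patient_id = pat_ids,
      study_date = format(study_date, "%Y-%m-%d"),
      birth_date = format(birth_date, "%Y-%m-%d"),
      sex = pat_sex[pat_of],
      view = view,
      body_part = "CHEST",
      width = width,
      height = height,
      manufacturer = manufacturer,
      department = department,
      report_text = report_text,
      label = label,
      rater1 = rate(),
      rater2 = rate(),
      rater3 = rate(),
      stringsAsFactors = FALSE
    )
    out
  })
}

# Fixed image geometry (fractions of the image side). Only intensity and
# noise are configurable; geometry constants keep the class signal learnable
# by a small network.
synth_geometry <- function(S) {
  list(
    entry_col   = 0.52,
    carina_row  = 0.40,
    stomach     = c(r0 = 0.68, r1 = 0.92, c0 = 0.52, c1 = 0.76), # lower third
    esophagus   = c(r0 = 0.46, r1 = 0.62, c0 = 0.46, c1 = 0.56), # mid band
    bronchial   = c(r0 = 0.44, r1 = 0.58, c0 = 0.64, c1 = 0.84), # lateral
    base        = 18000, lung = 27000, tube = 52000,
    tube_halfwidth = max(1L, round(S / 48))
  )
}

#' Class-specific tube-tip region
#'
#' Returns the rectangle (in 0-based pixel coordinates, rows then columns)
#' in which the rendered tube tip falls for a given class: a lower-third
#' "stomach" box for satisfactory, a mid "esophagus" band for malpositioned,
#' and a lateral "bronchial" branch region.
#'
#' @param label one of [ngt_classes()].
#' @param image_size image side in pixels.
#' @return named numeric vector `c(r0, r1, c0, c1)` in pixels (0-based).
#' @export
class_tip_region <- function(label, image_size) {
  g <- synth_geometry(image_size)
  box <- switch(label,
                satisfactory = g$stomach,
                malpositioned = g$esophagus,
                bronchial = g$bronchial,
                stop2("unknown label: ", label))
  round(box * (image_size - 1))
}

draw_polyline <- function(px, pts, value, halfwidth) {
  S <- nrow(px)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    nstep <- max(2L, ceiling(2 * max(abs(b - a))))
    t <- seq(0, 1, length.out = nstep)
    rr <- round(a[1] + t * (b[1] - a[1]))
    cc <- round(a[2] + t * (b[2] - a[2]))
    for (dr in -halfwidth:halfwidth) for (dc in -halfwidth:halfwidth) {
      r <- pmin(pmax(rr + dr, 1L), S)
      c <- pmin(pmax(cc + dc, 1L), S)
      px[cbind(r, c)] <- value
    }
  }
  px
}

#' Render one synthetic radiograph-like image
#'
#' Produces a 16-bit-range grayscale matrix with fixed anatomy (two bright
#' lung fields, a dark mediastinal band) and a bright polyline "tube"
#' descending from the top edge. The tube follows a common path to a carina
#' point and then terminates in the class-specific region given by
#' [class_tip_region()]. The record's manufacturer adds its configured
#' uniform intensity offset; the department adds a fixed vertical intensity
#' gradient; patient age adds a small uniform offset; Gaussian noise of sd
#' `noise_sd` is added last. Rendering is seeded per record, so a single
#' image is reproducible in isolation.
#'
#' @param record one manifest row (a list or single-row `data.frame`).
#' @param config a [synth_config()].
#' @return an object of class `synth_image`: list with `pixels` (matrix,
#'   gray levels in [0, 65535]), `tip_xy` (0-based `c(row, col)`), `label`,
#'   and `record_id`.
#' @export
render_image <- function(record, config) {
  stopifnot(inherits(config, "synth_config"))
  record <- as.list(record)
  label <- record$label
  if (is.null(label) || is.na(label) || !label %in% ngt_classes()) {
    stop2("record has no valid class label (got: ",
          if (is.null(label)) "NULL" else label, ")")
  }
  S <- config$image_size
  g <- synth_geometry(S)
  rid <- record$record_id %||% "anon"
  with_seed(config$seed, paste0("img_", rid), {
    px <- matrix(g$base, S, S)
    # lung fields: two bright ellipses
    rows <- matrix(seq_len(S), S, S)
    cols <- matrix(seq_len(S), S, S, byrow = TRUE)
    for (cc in c(0.30, 0.72)) {
      e <- ((rows / S - 0.45) / 0.30)^2 + ((cols / S - cc) / 0.17)^2
      px[e <= 1] <- g$lung
    }
    # mediastinal band
    px[, round(S * 0.45):round(S * 0.59)] <- g$base - 2000

    entry <- c(1, round(g$entry_col * S))
    carina <- c(round(g$carina_row * S), round(0.53 * S))
    box <- class_tip_region(label, S) + 1  # 1-based for drawing
    tip <- c(round(stats::runif(1, box["r0"], box["r1"])),
             round(stats::runif(1, box["c0"], box["c1"])))
    mid <- c(round((carina[1] + tip[1]) / 2),
             round((carina[2] + tip[2]) / 2 + stats::runif(1, -1, 1) * S / 40))
    pts <- rbind(entry, carina, mid, tip)
    px <- draw_polyline(px, pts, g$tube, g$tube_halfwidth)

    # metadata-driven intensity effects
    off <- config$manufacturer_levels[record$manufacturer %||% NA_character_]
    if (length(off) == 1 && !is.na(off)) px <- px + unname(off)
    dep_i <- match(record$department %||% NA_character_, config$department_levels)
    if (!is.na(dep_i)) {
      px <- px + (dep_i - 1) * 600 * (rows / S - 0.5)
    }
    if (!is.null(record$study_date) && !is.null(record$birth_date)) {
      age_y <- as.numeric(as.Date(record$study_date) - as.Date(record$birth_date)) / 365.25
      px <- px + 8 * (age_y - 67)
    }
    if (config$noise_sd > 0) {
      px <- px + stats::rnorm(S * S, 0, config$noise_sd)
    }
    px <- pmin(pmax(px, 0), 65535)
    structure(list(pixels = px,
                   tip_xy = c(row = tip[1] - 1L, col = tip[2] - 1L),
                   label = label,
                   record_id = rid),
              class = "synth_image")
  })
}

#' Render every image of a manifest
#'
#' @param manifest cohort manifest from [generate_manifest()].
#' @param config a [synth_config()].
#' @return named list of `synth_image` objects (names = record ids).
#' @export
render_cohort <- function(manifest, config) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    render_image(manifest[i, ], config)
  })
  names(out) <- manifest$record_id
  out
}

#' Write rendered images to disk
#'
#' PNG output is 8-bit grayscale (the finest the PNG writer supports);
#' choose `format = "tiff"` for lossless 16-bit storage. Files are named by
#' record id.
#'
#' @param images list of `synth_image` objects.
#' @param dir output directory (created if missing).
#' @param format `"png"` or `"tiff"`.
#' @return invisibly, the written file paths.
#' @export
write_images <- function(images, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(images, function(im) {
    f <- file.path(dir, paste0(im$record_id, ".", format))
    e <- EBImage::Image(t(im$pixels) / 65535)
    if (format == "tiff") {
      EBImage::writeImage(e, f, type = "tiff", bits.per.sample = 16L)
    } else {
      EBImage::writeImage(e, f, type = "png")
    }
    f
  }, "")
  invisible(paths)
}

#' Read images written by [write_images()]
#'
#' @param dir directory containing the image files.
#' @param record_ids record ids to read (order preserved).
#' @param format `"png"` or `"tiff"`.
#' @return named list of pixel matrices in [0, 65535].
#' @export
read_images <- function(dir, record_ids, format = c("png", "tiff")) {
  format <- match.arg(format)
  out <- lapply(record_ids, function(id) {
    f <- file.path(dir, paste0(id, ".", format))
    if (!file.exists(f)) stop2("missing image file: ", f)
    t(EBImage::imageData(EBImage::readImage(f))) * 65535
  })
  names(out) <- record_ids
  out
}

#' Generate synthetic latent embeddings with planted structure
#'
#' Draws rows from a Gaussian mixture: each group (class) has a mean vector,
#' optional metadata tags add per-level offset vectors, and isotropic
#' Gaussian noise of sd `noise_sd` is added. Stands in for the
#' global-average-pooling vectors of a trained network when testing the
#' attribution and drift modules in isolation.
#'
#' @param n_per_group named integer vector: rows per group.
#' @param centers numeric matrix, one row per group (rownames = group names;
#'   all rows share one dimension d).
#' @param tag_effects optional named list; each element is a list with
#'   `levels` (character), `probs` (sampling probabilities) and `offsets`
#'   (matrix levels x d added to rows with that level).
#' @param noise_sd isotropic noise sd (>= 0).
#' @param seed integer seed.
#' @return object of class `embedding_set`: list with `X` (n x d matrix,
#'   rownames = record ids), `labels` (factor), `tags` (data.frame).
#' @export
synth_embeddings <- function(n_per_group, centers, tag_effects = NULL,
                             noise_sd = 1, seed = 1) {
  centers <- as.matrix(centers)
  if (is.null(rownames(centers))) rownames(centers) <- names(n_per_group)
  if (length(n_per_group) != nrow(centers)) {
    stop2("n_per_group and centers must describe the same groups")
  }
  d <- ncol(centers)
  if (!is.null(tag_effects)) {
    for (nm in names(tag_effects)) {
      te <- tag_effects[[nm]]
      if (ncol(as.matrix(te$offsets)) != d) {
        stop2("tag effect '", nm, "' offsets have dimension ",
              ncol(as.matrix(te$offsets)), ", expected ", d)
      }
    }
  }
  n <- sum(n_per_group)
  with_seed(seed, "embeddings", {
    labels <- factor(rep(rownames(centers), n_per_group),
                     levels = rownames(centers))
    X <- centers[as.integer(labels), , drop = FALSE]
    tags <- data.frame(row.names = seq_len(n))
    if (!is.null(tag_effects)) {
      for (nm in names(tag_effects)) {
        te <- tag_effects[[nm]]
        off <- as.matrix(te$offsets)
        vals <- sample(te$levels, n, replace = TRUE,
                       prob = te$probs %||% NULL)
        X <- X + off[match(vals, te$levels), , drop = FALSE]
        tags[[nm]] <- vals
      }
    }
    if (noise_sd > 0) X <- X + matrix(stats::rnorm(n * d, 0, noise_sd), n, d)
    rownames(X) <- sprintf("emb%06d", seq_len(n))
    structure(list(X = X, labels = labels, tags = tags),
              class = "embedding_set")
  })
}

#' Specify a drift scenario
#'
#' @param kind one of `mean_shift` (embeddings: shift every dimension by
#'   `magnitude` per-dimension SDs), `manufacturer_swap` / `department_swap`
#'   (cohort: reassign every record to level `to`), `age_band` (cohort:
#'   keep only records whose age in years falls in `band = c(lo, hi)`,
#'   lo inclusive, hi exclusive).
#' @param magnitude shift size in per-dimension SD units (mean_shift).
#' @param band numeric `c(lo, hi)` age limits in years, ordered.
#' @param to replacement level (swap kinds).
#' @return object of class `drift_spec`.
#' @export
drift_spec <- function(kind = c("mean_shift", "manufacturer_swap",
                                "age_band", "department_swap"),
                       magnitude = NULL, band = NULL, to = NULL) {
  kind <- match.arg(kind)
  if (kind == "mean_shift") {
    if (is.null(magnitude) || !is.finite(magnitude)) {
      stop2("mean_shift requires a finite magnitude")
    }
  }
  if (kind == "age_band") {
    if (is.null(band) || length(band) != 2L || !all(is.finite(band))) {
      stop2("age_band requires finite band = c(lo, hi)")
    }
    if (band[1] > band[2]) stop2("age_band limits must be ordered")
  }
  if (kind %in% c("manufacturer_swap", "department_swap") && is.null(to)) {
    stop2(kind, " requires `to`, the replacement level")
  }
  structure(list(kind = kind, magnitude = magnitude, band = band, to = to),
            class = "drift_spec")
}

cohort_age_years <- function(cohort) {
  as.numeric(as.Date(cohort$study_date) - as.Date(cohort$birth_date)) / 365.25
}

#' Apply a drift scenario to a cohort or embedding set
#'
#' Returns a shifted or filtered copy; the input is untouched. A provenance
#' note describing the applied scenario is attached as attribute
#' `drift_note`.
#'
#' @param data a cohort manifest `data.frame` or an `embedding_set`.
#' @param spec a [drift_spec()].
#' @return same type as `data`.
#' @export
apply_drift <- function(data, spec) {
  stopifnot(inherits(spec, "drift_spec"))
  note <- paste0("drift:", spec$kind)
  if (spec$kind == "mean_shift") {
    if (!inherits(data, "embedding_set")) {
      stop2("mean_shift applies to embedding sets")
    }
    sds <- apply(data$X, 2, stats::sd)
    out <- data
    out$X <- sweep(data$X, 2, spec$magnitude * sds, `+`)
    attr(out, "drift_note") <- paste0(note, " magnitude=", spec$magnitude)
    return(out)
  }
  if (spec$kind == "age_band") {
    if (inherits(data, "embedding_set")) {
      if (is.null(data$tags$age_years)) {
        stop2("age_band on embeddings requires an age_years tag")
      }
      keep <- data$tags$age_years >= spec$band[1] &
        data$tags$age_years < spec$band[2]
      if (!any(keep)) stop2("empty cohort after age_band filtering")
      out <- data
      out$X <- data$X[keep, , drop = FALSE]
      out$labels <- data$labels[keep]
      out$tags <- data$tags[keep, , drop = FALSE]
    } else {
      age <- cohort_age_years(data)
      keep <- age >= spec$band[1] & age < spec$band[2]
      if (!any(keep)) stop2("empty cohort after age_band filtering")
      out <- data[keep, , drop = FALSE]
    }
    attr(out, "drift_note") <- paste0(note, " [", spec$band[1], ",",
                                      spec$band[2], ")")
    return(out)
  }
  # manufacturer_swap / department_swap on a cohort table
  field <- if (spec$kind == "manufacturer_swap") "manufacturer" else "department"
  if (inherits(data, "embedding_set")) {
    if (is.null(data$tags[[field]])) {
      stop2(spec$kind, " on embeddings requires a ", field, " tag")
    }
    out <- data
    out$tags[[field]] <- spec$to
  } else {
    if (is.null(data[[field]])) stop2("cohort lacks a ", field, " column")
    out <- data
    out[[field]] <- spec$to
  }
  attr(out, "drift_note") <- paste0(note, " to=", spec$to)
  out
}

#' Write / read a cohort manifest CSV
#'
#' The manifest is a plain CSV with the canonical header (record_id,
#' patient_id, study_date, birth_date, sex, view, body_part, width, height,
#' manufacturer, department, report_text, label, rater1, rater2, rater3).
#'
#' @param manifest cohort `data.frame`.
#' @param path file path.
#' @return `write_manifest`: invisibly, `path`; `read_manifest`: the
#'   `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Write / read an embedding set as a headered columnar file
#'
#' Columns: record_id, then the numeric embedding dimensions, then `label`
#' and any tag columns.
#'
#' @param es an `embedding_set`.
#' @param path file path (CSV).
#' @return `write_embeddings`: invisibly `path`; `read_embeddings`: the
#'   `embedding_set`.
#' @export
write_embeddings <- function(es, path) {
  stopifnot(inherits(es, "embedding_set"))
  X <- es$X
  colnames(X) <- paste0("dim", seq_len(ncol(X)))
  df <- data.frame(record_id = rownames(X), X,
                   label = as.character(es$labels),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(es$tags) > 0) df <- cbind(df, es$tags)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        comment.char = "#")
  dims <- grep("^(V|dim)[0-9]+$", names(df), value = TRUE)
  X <- as.matrix(df[, dims, drop = FALSE])
  rownames(X) <- df$record_id
  tagcols <- setdiff(names(df), c("record_id", "label", dims))
  structure(list(X = X,
                 labels = factor(df$label),
                 tags = df[, tagcols, drop = FALSE]),
            class = "embedding_set")
}
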