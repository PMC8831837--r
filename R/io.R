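#' Read a fundus image for measurement
#'
#' Reads a PNG or TIFF (8/16-bit, grayscale or RGB). RGB inputs are reduced
#' to the green channel, the standard choice for vessel contrast in fundus
#' photography; intensities are mapped to `[0, 1]`. Because retinal vessels
#' are darker than their background, the returned measurement image is
#' inverted to bright-vessel polarity, which is what the tracker consumes;
#' the un-inverted image is attached as `attr(,"display")`.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param invert invert to bright-vessel polarity (default `TRUE`).
#' @return intensity matrix in `[0, 1]` (bright vessels when `invert`).
#' @export
read_fundus_image <- function(path, invert = TRUE) {
  if (!file.exists(path)) stop("no such image file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(switch(ext,
                         png = png::readPNG(path),
                         tif = ,
                         tiff = tiff::readTIFF(path),
                         stop("unsupported image format: .", ext, call. = FALSE)),
                  error = function(e)
                    stop("could not read image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  img <- if (length(dim(arr)) == 3L) {
    arr[, , if (dim(arr)[3L] >= 3L) 2L else 1L]  # green channel of RGB
  } else arr
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  if (!all(is.finite(img))) stop("image contains non-finite pixels", call. = FALSE)
  out <- if (invert) 1 - img else img
  attr(out, "display") <- img
  out
}

#' Write an intensity matrix as an 8-bit grayscale PNG
#'
#' Values are clamped to `[0, 1]`.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Construct a per-image annotation
#'
#' One entry per vessel arm: a seed point near the optic-disc margin and a
#' distal target point, in continuous 1-based pixel coordinates
#' (x = column, y = row), plus the expert ROP stage label.
#'
#' @param stage `"none"`, `"1"`, `"2"` or `"3"` (aliases `stage1` etc. are
#'   accepted).
#' @param vessels list of entries `list(vessel, arm, seed, target,
#'   overlapped)` with `vessel` in artery/vein and `arm` in
#'   superior/inferior.
#' @param image optional image path the annotation refers to.
#' @return list of class `annotation`.
#' @export
annotation <- function(stage, vessels, image = NULL) {
  stage <- normalize_stage(stage)
  seen <- character(0)
  for (v in vessels) {
    if (!identical(v$vessel, "artery") && !identical(v$vessel, "vein"))
      stop("vessel must be 'artery' or 'vein'", call. = FALSE)
    if (!identical(v$arm, "superior") && !identical(v$arm, "inferior"))
      stop("arm must be 'superior' or 'inferior'", call. = FALSE)
    key <- paste(v$vessel, v$arm)
    if (key %in% seen)
      stop("duplicate annotation entry for ", key, call. = FALSE)
    seen <- c(seen, key)
    if (length(v$seed) != 2L || length(v$target) != 2L)
      stop("seed and target must be (x, y) pairs", call. = FALSE)
  }
  structure(list(schema = "vesselrt-annotation/1", coords = "1-based",
                 image = image, stage = stage, vessels = vessels),
            class = "annotation")
}

normalize_stage <- function(stage) {
  s <- tolower(as.character(stage))
  s <- sub("^stage", "", s)
  if (s %in% c("none", "no", "0")) return("none")
  if (s %in% c("1", "2", "3")) return(paste0("stage", s))
  stop("stage must be one of none, 1, 2, 3", call. = FALSE)
}

#' Read / write annotation JSON
#'
#' @param path JSON file path.
#' @return [read_annotation()] returns an `annotation`;
#'   `write_annotation()` returns `path` invisibly.
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "vesselrt-annotation/1"))
    stop("not a vesselrt annotation file: ", path, call. = FALSE)
  vessels <- lapply(obj$vessels, function(v)
    list(vessel = v$vessel, arm = v$arm,
         seed = as.numeric(unlist(v$seed)),
         target = as.numeric(unlist(v$target)),
         overlapped = isTRUE(v$overlapped)))
  annotation(stage = obj$stage, vessels = vessels, image = obj$image)
}

#' @rdname read_annotation
#' @param ann an `annotation`.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "annotation"))
  jsonlite::write_json(unclass(ann), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Measure a batch of annotated images
#'
#' Runs [measure_eye()] on each image/annotation pair and assembles a
#' results table: one row per image with the stage label, TAA/TVA (degrees),
#' TAW/TVW (pixels), fallback flags and diagnostics. Failed images produce
#' an error row rather than aborting the batch.
#'
#' @param images character vector of image paths, or a list of intensity
#'   matrices (bright-vessel polarity).
#' @param annotations list of `annotation` objects (or JSON paths).
#' @param params a [tracking_params()] list.
#' @return data frame with columns `image`, `stage`, `taa`, `tva`, `taw`,
#'   `tvw`, `taw_inferior_only`, `tvw_inferior_only`, `error`, `notes`.
#' @export
measure_batch <- function(images, annotations, params = tracking_params()) {
  if (length(images) == 0L) stop("no images supplied", call. = FALSE)
  if (length(images) != length(annotations))
    stop("need one annotation per image", call. = FALSE)
  rows <- list()
  for (i in seq_along(images)) {
    id <- if (is.character(images)) images[[i]] else sprintf("image_%03d", i)
    row <- data.frame(image = id, stage = NA_character_,
                      taa = NA_real_, tva = NA_real_,
                      taw = NA_real_, tvw = NA_real_,
                      taw_inferior_only = FALSE, tvw_inferior_only = FALSE,
                      error = NA_character_, notes = "")
    res <- tryCatch({
      img <- if (is.character(images)) read_fundus_image(images[[i]])
             else as_intensity_image(images[[i]])
      ann <- annotations[[i]]
      if (is.character(ann)) ann <- read_annotation(ann)
      m <- measure_eye(img, ann, params)
      row$stage <- ann$stage
      row$taa <- m$taa; row$tva <- m$tva
      row$taw <- m$taw; row$tvw <- m$tvw
      row$taw_inferior_only <- m$taw_inferior_only
      row$tvw_inferior_only <- m$tvw_inferior_only
      row$notes <- paste(m$flags, collapse = "; ")
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a results table CSV
#'
#' Lossless round-trip of the [measure_batch()] results layout.
#'
#' @param path CSV path.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(taw_inferior_only = "logical",
                                 tvw_inferior_only = "logical"))
}

#' @rdname read_results
#' @param results a results data frame.
#' @export
write_results <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' Per-stage cohort report
#'
#' Builds the per-stage summary layout (n, median, min, max, mean, sd) for
#' each measured variable from a results or cohort table, the one-way ANOVA
#' p-value per variable, the Tukey pairwise comparisons, and the pairwise
#' Pearson correlation table across variables.
#'
#' @param results data frame with `stage` and variable columns.
#' @param variables variable columns to report (defaults to the angle/width
#'   columns present).
#' @param exclude_inferior_only drop rows whose TAW is an inferior-only
#'   fallback from the TAW correlations (the default keeps them).
#' @return list of class `cohort_report` with `summaries`, `anova`,
#'   `tukey`, `correlations`.
#' @export
cohort_report <- function(results,
                          variables = intersect(c("TAA", "TVA", "TAW", "TVW",
                                                  "taa", "tva", "taw", "tvw"),
                                                names(results)),
                          exclude_inferior_only = FALSE) {
  if (length(unique(results$stage[!is.na(results$stage)])) < 2L)
    stop("need at least 2 stage groups for a cohort report", call. = FALSE)
  if (length(variables) == 0L) stop("no measurement variables found", call. = FALSE)
  summaries <- list(); anv <- list(); tuk <- list()
  for (v in variables) {
    vals <- results[[v]]
    ok <- is.finite(vals) & !is.na(results$stage)
    sub <- data.frame(value = vals[ok], stage = results$stage[ok])
    sm <- do.call(rbind, lapply(split(sub$value, sub$stage), function(x)
      data.frame(n = length(x), median = stats::median(x), min = min(x),
                 max = max(x), mean = mean(x), sd = stats::sd(x))))
    sm <- cbind(stage = rownames(sm), variable = toupper(v), sm)
    rownames(sm) <- NULL
    summaries[[v]] <- sm
    if (all(sm$n >= 2)) {
      anv[[v]] <- anova_oneway(data.frame(value = sub$value, group = sub$stage))
      tuk[[v]] <- tukey_hsd(data.frame(value = sub$value, group = sub$stage))
    }
  }
  cors <- list()
  if (length(variables) >= 2L) {
    pairs <- utils::combn(variables, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1L, j]; b <- pairs[2L, j]
      x <- results[[a]]; y <- results[[b]]
      keep <- is.finite(x) & is.finite(y)
      if (exclude_inferior_only && "taw_inferior_only" %in% names(results) &&
          "TAW" %in% toupper(c(a, b)))
        keep <- keep & !results$taw_inferior_only
      if (sum(keep) >= 3L && stats::sd(x[keep]) > 0 && stats::sd(y[keep]) > 0) {
        ct <- pearson(x[keep], y[keep])
        cors[[length(cors) + 1L]] <-
          data.frame(var1 = toupper(a), var2 = toupper(b), r = ct$r,
                     n = ct$n, t = ct$t, p = ct$p)
      }
    }
  }
  structure(list(summaries = do.call(rbind, summaries),
                 anova = anv, tukey = tuk,
                 correlations = if (length(cors)) do.call(rbind, cors) else NULL),
            class = "cohort_report")
}

#' Render a cohort report as Markdown
#'
#' @param report a [cohort_report()].
#' @param path optional output file.
#' @return character vector of Markdown lines (invisibly when writing).
#' @export
format_cohort_report <- function(report, path = NULL) {
  fmt_p <- function(p) ifelse(p < 1e-4, "<0.0001", sprintf("%.4f", p))
  lines <- c("# Temporal vessel geometry by ROP stage", "")
  for (v in names(report$anova)) {
    a <- report$anova[[v]]
    sm <- report$summaries[report$summaries$variable == toupper(v), ]
    lines <- c(lines, sprintf("## %s", toupper(v)), "",
               "| stage | n | median | min | max | mean +/- sd |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %d | %.2f | %.2f | %.2f | %.2f +/- %.2f |",
                       sm$stage, sm$n, sm$median, sm$min, sm$max, sm$mean, sm$sd),
               "",
               sprintf("One-way ANOVA: F(%d, %d) = %.3f, p %s",
                       a$df_between, a$df_within, a$F,
                       ifelse(a$p < 1e-4, "< 0.0001", sprintf("= %.4f", a$p))),
               "")
    tk <- report$tukey[[v]]
    if (!is.null(tk)) {
      sig <- tk[tk$significant, , drop = FALSE]
      lines <- c(lines,
                 if (nrow(sig)) sprintf("Tukey significant pairs (p < 0.05): %s",
                                        paste(sig$pair, collapse = ", "))
                 else "Tukey: no significant pairs", "")
    }
  }
  if (!is.null(report$correlations)) {
    co <- report$correlations
    lines <- c(lines, "## Pairwise Pearson correlations", "",
               "| pair | r | n | p |", "|---|---|---|---|",
               sprintf("| %s-%s | %.3f | %d | %s |",
                       co$var1, co$var2, co$r, co$n, fmt_p(co$p)), "")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Simulate phantoms and/or cohorts from a JSON specification
#'
#' The spec is a JSON object with optional members `phantoms` (a list of
#' eye-phantom descriptions: `angle_artery`, `angle_vein`, `width_artery`,
#' `width_vein`, `noise_sigma`, `seed`, ...) and `cohort` (`n_scale`,
#' `seed`, optional `correlation` with `variables` and `matrix`). Outputs
#' (PNG images, JSON truth/annotations, CSV cohort) are written under
#' `out_dir`, reproducibly by seed.
#'
#' @param spec_path JSON file path.
#' @param out_dir output directory (created if needed).
#' @param seed overriding base seed (optional).
#' @return named list of written file paths.
#' @export
simulate_from_spec <- function(spec_path, out_dir, seed = NULL) {
  spec <- tryCatch(jsonlite::fromJSON(spec_path, simplifyVector = TRUE),
                   error = function(e)
                     stop("invalid simulation spec: ", conditionMessage(e),
                          call. = FALSE))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- list()
  phantoms <- spec$phantoms
  if (!is.null(phantoms)) {
    if (is.data.frame(phantoms))
      phantoms <- split(phantoms, seq_len(nrow(phantoms)))
    for (i in seq_along(phantoms)) {
      ph <- as.list(phantoms[[i]])
      bad <- c(if (!is.null(ph$width_artery) && ph$width_artery <= 0) "width_artery",
               if (!is.null(ph$width_vein) && ph$width_vein <= 0) "width_vein",
               if (!is.null(ph$noise_sigma) && ph$noise_sigma < 0) "noise_sigma")
      if (length(bad))
        stop("invalid phantom spec fields: ", paste(bad, collapse = ", "),
             call. = FALSE)
      ps <- phantom_eye_spec(
        angle_artery = ph$angle_artery %||% 120,
        angle_vein = ph$angle_vein,
        width_artery = ph$width_artery %||% 4,
        width_vein = ph$width_vein %||% 6,
        noise_sigma = ph$noise_sigma %||% 0,
        seed = (if (!is.null(seed)) seed + i else ph$seed %||% i))
      rp <- render_phantom(ps)
      img_path <- file.path(out_dir, sprintf("phantom_%03d.png", i))
      ann_path <- file.path(out_dir, sprintf("phantom_%03d.annotation.json", i))
      write_image_png(rp$image, img_path)
      ann <- truth_annotation(rp$truth, stage = ph$stage %||% "none")
      ann$image <- basename(img_path)
      write_annotation(ann, ann_path)
      truth_path <- file.path(out_dir, sprintf("phantom_%03d.truth.json", i))
      jsonlite::write_json(
        list(true_angle_artery = rp$truth$true_angle_artery,
             true_angle_vein = rp$truth$true_angle_vein,
             widths = lapply(rp$truth$arms, function(a)
               list(label = a$label, width = a$width))),
        truth_path, auto_unbox = TRUE, digits = NA, null = "null")
      written[[length(written) + 1L]] <- c(img_path, ann_path, truth_path)
    }
  }
  if (!is.null(spec$cohort)) {
    ch <- spec$cohort
    corr <- NULL
    if (!is.null(ch$correlation)) {
      corr <- matrix(unlist(ch$correlation$matrix),
                     nrow = length(ch$correlation$variables), byrow = TRUE,
                     dimnames = list(ch$correlation$variables,
                                     ch$correlation$variables))
    }
    cs <- cohort_spec(n_scale = ch$n_scale %||% 1, correlation = corr,
                      seed = (if (!is.null(seed)) seed else ch$seed %||% 1L))
    tab <- sample_cohort(cs)
    cohort_path <- file.path(out_dir, "cohort.csv")
    utils::write.csv(tab, cohort_path, row.names = FALSE)
    written$cohort <- cohort_path
  }
  if (length(written) == 0L)
    stop("simulation spec contains neither phantoms nor cohort", call. = FALSE)
  written
}

`%||%` <- function(a, b) if (is.null(a)) b else a
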