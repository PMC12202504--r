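#' Render per-slice fat attenuation maps
#'
#' Writes one PNG per slice that contains adipose voxels, colouring each fat
#' voxel by its HU on a fixed colour scale spanning exactly the fat window,
#' with a colour-bar and the slice-mean fat HU in the title. Non-fat voxels
#' are shown as a dim anatomical backdrop. A CSV index maps slice number to
#' mean fat HU and fat-voxel count. If the fat mask is empty everywhere, no
#' images are produced, the CSV is empty and a warning is raised.
#'
#' @param grid an [image_grid()].
#' @param fat adipose [binary_mask()] aligned with `grid`.
#' @param out_dir output directory (created if needed).
#' @param window the [fat_window()] fixing the colour-scale bounds.
#' @param palette name of a multi-hue perceptually uniform palette understood
#'   by [grDevices::hcl.colors()] (default `"viridis"`).
#' @param axis slice axis (default 3, the acquisition axis).
#' @return Invisibly, a data.frame (`slice`, `mean_hu`, `n_fat`) with
#'   attributes `scale_lo`/`scale_hi` (the colour-scale bounds in HU) and
#'   `files`.
#' @export
render_fat_slices <- function(grid, fat, out_dir, window = fat_window(),
                              palette = "viridis", axis = 3L) {
  assert_aligned(grid, fat, "fat mask")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(grid$values)
  slices <- which(apply(fat$values, axis, any))
  idx <- data.frame(slice = integer(0), mean_hu = numeric(0),
                    n_fat = integer(0))
  files <- character(0)
  if (length(slices) == 0L) {
    warning("fat mask contains no voxels; nothing rendered")
  } else {
    cols <- grDevices::hcl.colors(256, palette)
    for (s in slices) {
      img <- drop(slab(grid$values, axis, s))
      msk <- drop(slab(fat$values, axis, s))
      hu <- img
      hu[!msk] <- NA
      mean_hu <- mean(img[msk])
      n_fat <- sum(msk)
      idx <- rbind(idx, data.frame(slice = s, mean_hu = mean_hu,
                                   n_fat = n_fat))
      f <- file.path(out_dir, sprintf("slice_%04d.png", s))
      grDevices::png(f, width = 720, height = 560)
      graphics::layout(matrix(1:2, 1), widths = c(5, 1))
      graphics::par(mar = c(2, 2, 3, 1))
      # backdrop: full image in grey, then fat voxels on the HU colour scale
      graphics::image(seq_len(nrow(img)), seq_len(ncol(img)), img,
                      col = grDevices::grey.colors(64, 0.05, 0.5),
                      axes = FALSE, xlab = "", ylab = "", useRaster = TRUE)
      graphics::image(seq_len(nrow(hu)), seq_len(ncol(hu)),
                      pmin(pmax(hu, window$lo_hu), window$hi_hu),
                      zlim = c(window$lo_hu, window$hi_hu), col = cols,
                      add = TRUE, useRaster = TRUE)
      graphics::title(sprintf("slice %d - mean fat HU %.1f (n = %d)",
                              s, mean_hu, n_fat))
      graphics::par(mar = c(2, 1, 3, 3))
      bar <- seq(window$lo_hu, window$hi_hu, length.out = 256)
      graphics::image(1, bar, matrix(bar, 1), col = cols, axes = FALSE,
                      xlab = "", ylab = "")
      graphics::axis(4)
      graphics::mtext("HU", side = 3, line = 0.5)
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  csv <- file.path(out_dir, "slice_index.csv")
  utils::write.csv(idx, csv, row.names = FALSE)
  attr(idx, "scale_lo") <- window$lo_hu
  attr(idx, "scale_hi") <- window$hi_hu
  attr(idx, "files") <- files
  invisible(idx)
}

#' Assemble a Markdown analysis report
#'
#' Combines the available stage outputs -- per-subject measurements, group
#' comparisons, logistic fits and ROC summaries -- into a single Markdown
#' document with a provenance section. Sections whose input is missing are
#' marked absent; the build still succeeds. Given identical inputs the
#' report body is byte-identical (no timestamps).
#'
#' @param measurements optional data.frame of per-subject PVAT measurements.
#' @param tests optional [compare_groups()] result.
#' @param screen optional [univariate_screen()] result.
#' @param fit optional [multivariate_logistic()] result.
#' @param rocs optional named list of [roc_analysis()] results.
#' @param out_path output `.md` path.
#' @param provenance named list recorded verbatim (seeds, specs, versions).
#' @return `out_path`, invisibly.
#' @export
build_report <- function(measurements = NULL, tests = NULL, screen = NULL,
                         fit = NULL, rocs = NULL, out_path,
                         provenance = list()) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, ...)
  add("# PVAT attenuation analysis report", "")

  add("## Per-subject measurements", "")
  if (is.null(measurements)) add("*Section absent: no measurements supplied.*", "")
  else add(md_table(measurements), "")

  add("## Group comparison", "")
  if (is.null(tests)) add("*Section absent: no group tests supplied.*", "")
  else add(md_table(as.data.frame(tests)), "")

  add("## Logistic modelling", "")
  if (is.null(screen) && is.null(fit)) {
    add("*Section absent: no model output supplied.*", "")
  } else {
    if (!is.null(screen)) {
      add("### Univariate screen", "", md_table(screen$fits), "",
          paste0("Advancing (p < ", screen$alpha, "): ",
                 if (length(screen$advancing))
                   paste(screen$advancing, collapse = ", ") else "(none)"),
          "")
    }
    if (!is.null(fit))
      add("### Multivariate model", "", md_table(fit$coefficients), "")
  }

  add("## ROC analysis", "")
  if (is.null(rocs) || length(rocs) == 0L) {
    add("*Section absent: no ROC results supplied.*", "")
  } else {
    roc_df <- do.call(rbind, lapply(names(rocs), function(nm) {
      r <- rocs[[nm]]
      data.frame(marker = nm, direction = r$direction,
                 auc = round(r$auc, 3),
                 youden_cutoff = round(r$youden_cutoff, 3),
                 sensitivity = round(r$youden_sensitivity, 3),
                 specificity = round(r$youden_specificity, 3))
    }))
    add(md_table(roc_df), "")
  }

  add("## Provenance", "")
  if (length(provenance) == 0L) add("(none recorded)", "")
  else for (nm in names(provenance))
    add(paste0("- ", nm, ": ", paste(format(provenance[[nm]]),
                                     collapse = " ")))
  writeLines(ln, out_path)
  invisible(out_path)
}

md_table <- function(df) {
  df <- as.data.frame(df)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 6, format = "g") else
      as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- if (nrow(df) == 0L) character(0) else
    apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
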