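# Manifests, PNG sample loading, resizing, report writing, config hashing.

#' Bilinear resize of a matrix
#' @param m numeric matrix.
#' @param oh,ow output size.
#' @export
resize_bilinear <- function(m, oh, ow) {
  m <- as.matrix(m)
  interp_matrix(oh, nrow(m)) %*% m %*% t(interp_matrix(ow, ncol(m)))
}

#' Nearest-neighbor resize of a matrix
#' @param m numeric matrix.
#' @param oh,ow output size.
#' @export
resize_nearest <- function(m, oh, ow) {
  m <- as.matrix(m)
  ri <- pmin(pmax(round((seq_len(oh) - 0.5) * nrow(m) / oh + 0.5), 1), nrow(m))
  ci <- pmin(pmax(round((seq_len(ow) - 0.5) * ncol(m) / ow + 0.5), 1), ncol(m))
  m[ri, ci, drop = FALSE]
}

# separable Gaussian blur (reflects at borders via kernel renormalization)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  K1 <- band_matrix(nrow(m), k, r)
  K2 <- band_matrix(ncol(m), k, r)
  K1 %*% m %*% t(K2)
}

band_matrix <- function(n, k, r) {
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- (i - r):(i + r)
    ok <- idx >= 1 & idx <= n
    M[i, idx[ok]] <- k[ok] / sum(k[ok])
  }
  M
}

#' Load and validate a dataset manifest
#'
#' Expects a CSV with header \code{id,image_path,mask_path,fold}. Paths are
#' resolved relative to the manifest location; ids must be unique, folds
#' integer, and all referenced files present.
#'
#' @param path manifest CSV path.
#' @return data.frame with absolute paths and integer folds.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("id", "image_path", "mask_path", "fold")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns ", paste(need, collapse = ","))
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicated id in manifest: ", paste(unique(dup), collapse = ", "))
  fold <- suppressWarnings(as.integer(df$fold))
  bad <- which(is.na(fold) | suppressWarnings(as.numeric(df$fold)) != fold)
  if (length(bad)) stop("non-integer fold value in manifest row ", bad[1],
                        " (id ", df$id[bad[1]], ")")
  base <- dirname(normalizePath(path))
  abspath <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  df$image_path <- abspath(df$image_path)
  df$mask_path <- abspath(df$mask_path)
  missing <- c(df$image_path[!file.exists(df$image_path)],
               df$mask_path[!file.exists(df$mask_path)])
  if (length(missing)) stop("missing files referenced by manifest: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  df$fold <- fold
  df
}

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                       c(1, 2), mean)
  a
}

#' Load one manifest row as a working-resolution sample
#'
#' The image is resized bilinearly, min-max normalized to [0, 1] (a constant
#' image maps to all zeros); the mask is resized with nearest neighbor and
#' binarized at 128/255.
#'
#' @param row one manifest row (data.frame or list with id, image_path,
#'   mask_path, fold).
#' @param image_size working resolution.
#' @return "image_sample" list (image, mask, id, fold).
#' @export
load_sample <- function(row, image_size) {
  img <- resize_bilinear(read_gray_png(row$image_path), image_size, image_size)
  r <- range(img)
  img <- if (r[2] > r[1]) (img - r[1]) / (r[2] - r[1]) else img * 0
  mask <- resize_nearest(read_gray_png(row$mask_path), image_size, image_size)
  mask <- (mask >= 128 / 255) + 0
  structure(list(image = img, mask = mask, id = row$id,
                 fold = as.integer(row$fold)),
            class = "image_sample")
}

#' Load every sample referenced by a manifest
#' @param manifest data.frame from \code{\link{load_manifest}}.
#' @param image_size working resolution.
#' @return named list of samples (by id).
#' @export
load_samples <- function(manifest, image_size) {
  out <- lapply(seq_len(nrow(manifest)), function(i)
    load_sample(manifest[i, ], image_size))
  names(out) <- manifest$id
  out
}

fmt6 <- function(x) {
  if (is.numeric(x)) signif(x, 6) else x
}

round_rec <- function(x) {
  if (is.list(x)) return(lapply(x, round_rec))
  fmt6(x)
}

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; changes whenever any field
#' changes.
#' @param config any list-like configuration.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

write_json_report <- function(x, path) {
  x <- round_rec(x)
  # sorted keys + fixed float format for byte-stable output
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && all(nzchar(names(v)))) {
      v <- v[order(names(v))]
      return(lapply(v, sort_rec))
    }
    if (is.list(v)) return(lapply(v, sort_rec))
    v
  }
  writeLines(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null", force = TRUE), path)
  invisible(path)
}

#' Write the standard result files of a run
#'
#' Emits (when the corresponding element is present in \code{results}):
#' per-image metrics CSV (\code{metrics.csv}), fold-summary JSON
#' (\code{fold_summary.json}), pairwise comparison JSON
#' (\code{comparisons.json}), and an ablation table CSV
#' (\code{ablation.csv}). Every JSON carries the config hash and seed;
#' numbers are written with 6 significant digits and sorted keys so reruns
#' are byte-identical.
#'
#' @param results list with any of \code{metrics} (data.frame),
#'   \code{fold_summary}, \code{comparisons}, \code{ablation} (data.frame),
#'   plus \code{config} and \code{seed}.
#' @param out_dir output directory.
#' @return character vector of files written.
#' @export
write_reports <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(results$config)
  written <- character(0)
  meta <- list(config_hash = hash, seed = results$seed)
  if (!is.null(results$metrics)) {
    p <- file.path(out_dir, "metrics.csv")
    df <- results$metrics
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt6)
    write.csv(df, p, row.names = FALSE)
    written <- c(written, p)
  }
  if (!is.null(results$fold_summary)) {
    p <- file.path(out_dir, "fold_summary.json")
    fs <- results$fold_summary
    write_json_report(c(meta, list(
      fold_means = as.list(fs$fold_means),
      summary = as.list(fs$summary))), p)
    written <- c(written, p)
  }
  if (!is.null(results$comparisons)) {
    p <- file.path(out_dir, "comparisons.json")
    write_json_report(c(meta, list(comparisons = lapply(results$comparisons,
                                                        unclass))), p)
    written <- c(written, p)
  }
  if (!is.null(results$ablation)) {
    p <- file.path(out_dir, "ablation.csv")
    df <- results$ablation
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt6)
    write.csv(df, p, row.names = FALSE)
    written <- c(written, p)
  }
  written
}
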