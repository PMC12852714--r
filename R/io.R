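## Readers and writers for the plain-text formats the analysis consumes:
## expression tables (GlioVis-style exports), survival tables, viability
## plate readouts, GMT gene-set files, threshold/config YAML and one- or
## two-channel stain images (PNG/TIFF via EBImage).

.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read an expression matrix
#'
#' Reads a TSV/CSV table whose first column holds gene symbols and whose
#' remaining columns are one numeric column per sample (header row = sample
#' ids). The delimiter (tab or comma) is sniffed from the first line. Gene
#' symbols are upper-cased and hyphen-stripped on ingest; duplicate symbols
#' and non-numeric cells are format errors.
#'
#' @param path path to the expression table.
#' @param groupFile optional path to a two-column table (sample id, subgroup
#'   label) assigning samples to molecular subgroups.
#' @return an [ExprMatrix-class].
#' @export
readExpression <- function(path, groupFile = NULL) {
  sep <- .sniffSep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE, quote = "\"",
                   comment.char = "")
  if (ncol(df) < 2L) stop("expression table needs a gene column plus samples")
  genes <- normalizeSymbols(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- df[, -1L, drop = FALSE]
  numeric_ok <- vapply(vals, is.numeric, logical(1))
  if (!all(numeric_ok))
    stop("non-numeric expression column(s): ",
         paste(names(vals)[!numeric_ok], collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- genes
  groups <- NULL
  if (!is.null(groupFile)) {
    gdf <- read.table(groupFile, header = TRUE, sep = .sniffSep(groupFile),
                      stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(gdf) < 2L) stop("group table needs sample and group columns")
    groups <- stats::setNames(as.character(gdf[[2L]]), as.character(gdf[[1L]]))
  }
  ExprMatrix(m, sampleGroups = groups)
}

#' Write / read an expression matrix
#'
#' `writeExpression` writes the transpose-free genes-by-samples layout that
#' [readExpression()] consumes (tab-separated, first column `gene`).
#'
#' @param x an [ExprMatrix-class].
#' @param path output path.
#' @export
writeExpression <- function(x, path) {
  m <- exprValues(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival table
#'
#' Reads a CSV/TSV with columns `subject_id` (optional), `time_days`,
#' `event` (0/1) and `group`. Non-positive times and event codes outside
#' \{0, 1\} are rejected.
#'
#' @param path path to the table.
#' @return data.frame with columns `subject_id`, `time_days`, `event`
#'   (logical), `group`.
#' @export
readSurvival <- function(path) {
  df <- read.table(path, header = TRUE, sep = .sniffSep(path),
                   stringsAsFactors = FALSE)
  need <- c("time_days", "event", "group")
  if (!all(need %in% names(df)))
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$time_days) || any(!is.finite(df$time_days)) ||
      any(df$time_days <= 0))
    stop("time_days must be positive finite numbers")
  if (!all(df$event %in% c(0, 1)))
    stop("event must be coded 0 (censored) or 1 (death observed)")
  data.frame(
    subject_id = if ("subject_id" %in% names(df))
      as.character(df$subject_id) else paste0("s", seq_len(nrow(df))),
    time_days = df$time_days,
    event = df$event == 1,
    group = as.character(df$group),
    stringsAsFactors = FALSE
  )
}

#' Read a viability plate table
#'
#' Columns: `label` (treatment), `dose_uM` (0 = untreated), `timepoint_h`,
#' `od540`, `od650`, optionally `plate`.
#'
#' @param path path to the table.
#' @return validated data.frame.
#' @export
readViability <- function(path) {
  df <- read.table(path, header = TRUE, sep = .sniffSep(path),
                   stringsAsFactors = FALSE)
  need <- c("label", "dose_uM", "timepoint_h", "od540", "od650")
  if (!all(need %in% names(df)))
    stop("viability table needs columns: ", paste(need, collapse = ", "))
  if (any(df$dose_uM < 0)) stop("doses must be non-negative")
  df
}

#' Write / read ratio-score tables
#'
#' Scores are serialized as a tab-separated long-format table with full
#' numeric precision (`%.17g`), so a write/read round trip reproduces every
#' field exactly.
#'
#' @param scores data.frame as returned by [scorePanel()].
#' @param path file path.
#' @return `readScores` returns the score data.frame.
#' @export
writeScores <- function(scores, path) {
  out <- scores
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  for (cl in intersect(c("ratio", "rho"), names(df)))
    df[[cl]] <- as.numeric(df[[cl]])
  df
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path path to the GMT file.
#' @param role signature role to assign (default `"subtype"`).
#' @return named list of [GeneSignature-class] objects.
#' @export
readGmt <- function(path, role = "subtype") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need name, description, >= 1 gene)")
    GeneSignature(parts[1L], parts[-(1:2)], role = role)
  })
  stats::setNames(sigs, vapply(sigs, function(s) s@name, ""))
}

#' Read tier thresholds from a YAML config
#'
#' Recognized keys: `weak_r`, `weak_p`, `moderate_r`, `moderate_p`,
#' `strong_r`, `strong_p`, `relax_weak_p`. Missing keys keep the published
#' defaults.
#'
#' @param path path to the YAML file.
#' @return a [TierThresholds-class].
#' @export
readThresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  d <- TierThresholds()
  pick <- function(key, dflt) if (!is.null(cfg[[key]])) cfg[[key]] else dflt
  TierThresholds(
    weakR = pick("weak_r", d@weakR), weakP = pick("weak_p", d@weakP),
    moderateR = pick("moderate_r", d@moderateR),
    moderateP = pick("moderate_p", d@moderateP),
    strongR = pick("strong_r", d@strongR),
    strongP = pick("strong_p", d@strongP),
    relaxWeakP = isTRUE(pick("relax_weak_p", d@relaxWeakP))
  )
}

#' Read a one- or two-channel stain image
#'
#' Reads PNG or TIFF via EBImage. Two-channel (or multi-frame) images are
#' split into marker and nuclear channels by index; single-channel images
#' are treated as nuclear-only (absent marker). The physical pixel size is
#' taken from `pixelSizeUm`, or from a YAML sidecar `<path>.yaml` with key
#' `pixel_size_um` when the argument is missing.
#'
#' @param path image path (.png/.tif/.tiff).
#' @param pixelSizeUm pixel edge length in micrometres.
#' @param markerChannel,nuclearChannel channel indices for two-channel
#'   images.
#' @return a [StainImage-class].
#' @export
readStainImage <- function(path, pixelSizeUm = NULL,
                           markerChannel = 1L, nuclearChannel = 2L) {
  if (is.null(pixelSizeUm)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar))
      stop("pixelSizeUm not given and no sidecar config at ", sidecar)
    cfg <- yaml::read_yaml(sidecar)
    if (is.null(cfg$pixel_size_um))
      stop("sidecar config lacks key 'pixel_size_um'")
    pixelSizeUm <- cfg$pixel_size_um
  }
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  nd <- length(dim(dat))
  if (nd == 2L) {
    return(StainImage(marker = NULL, nuclear = dat,
                      pixelSizeUm = pixelSizeUm))
  }
  nchan <- dim(dat)[3L]
  if (max(markerChannel, nuclearChannel) > nchan)
    stop("image has ", nchan, " channel(s); requested channels ",
         markerChannel, "/", nuclearChannel, " unavailable")
  StainImage(marker = dat[, , markerChannel],
             nuclear = dat[, , nuclearChannel],
             pixelSizeUm = pixelSizeUm)
}

#' Write a stain image
#'
#' Writes marker and nuclear channels as a 2-frame TIFF (or a single-frame
#' image when the marker is absent), clamped to \[0, 1\].
#'
#' @param image a [StainImage-class].
#' @param path output path (.tif or .png).
#' @export
writeStainImage <- function(image, path) {
  clamp <- function(m) pmin(pmax(m, 0), 1)
  if (length(image@marker)) {
    arr <- array(0, dim = c(dim(image@nuclear), 2L))
    arr[, , 1L] <- clamp(image@marker)
    arr[, , 2L] <- clamp(image@nuclear)
  } else {
    arr <- clamp(image@nuclear)
  }
  EBImage::writeImage(EBImage::Image(arr), path)
  invisible(path)
}
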