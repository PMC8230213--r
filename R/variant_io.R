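# Reading and writing the formats the pipeline touches.
#
# Conventions: coordinates are 1-based inclusive as in VCF; indels are kept
# as given (no re-normalization); VAF is stored on the percent scale; the
# join key between calls and annotations is (chrom, pos, ref, alt) after
# multi-allelic splitting. Missing values are written as '.' in TSV output.

.ENUM_MAPS <- list(
  sift = .SIFT_LEVELS,
  polyphen = .POLYPHEN_LEVELS,
  consequence = .CONSEQUENCES,
  gender = c("male", "female"),
  site = .SITES,
  t_stage = paste0("T", 1:4),
  n_stage = paste0("N", 0:2),
  m_stage = paste0("M", 0:1),
  overall_stage = .STAGES
)

.normEnum <- function(x, field) {
  # case-insensitive; spaces and hyphens collapse to underscores
  lv <- .ENUM_MAPS[[field]]
  y <- gsub("[ -]+", "_", trimws(tolower(as.character(x))))
  canon <- gsub("[ -]+", "_", tolower(lv))
  out <- lv[match(y, canon)]
  bad <- !is.na(x) & x != "." & nzchar(as.character(x)) & is.na(out)
  if (any(bad))
    stop(sprintf("unrecognized %s value(s): %s", field,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  if ("missing" %in% lv) out[is.na(out)] <- "missing"
  out
}

.asLogicalCol <- function(x) {
  if (is.logical(x)) return(x)
  y <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[y %in% c("true", "t", "1", "yes")] <- TRUE
  out[y %in% c("false", "f", "0", "no")] <- FALSE
  out
}

#' Read per-sample variant calls from a VCF file
#'
#' Parses a VCF v4.x file into the internal call table. Multi-allelic
#' records are split into one row per ALT allele; the variant allele
#' fraction is computed from the `AD` allele depths when present, falling
#' back to an `AF` fraction field, and left missing (with a record-level
#' warning) when neither is available.
#'
#' @param path path to a VCF file
#' @param sampleId sample identifier; defaults to the VCF sample column
#'   name, or the file basename when the VCF has no genotype columns
#' @return data.frame of calls (one row per sample x allele), columns
#'   `sample_id, chrom, pos, ref, alt, qual, depth, alt_depth, vaf_percent`
#' @export
readVcfCalls <- function(path, sampleId = NULL) {
  if (!file.exists(path))
    stop(sprintf("VCF file not found: %s", path), call. = FALSE)
  .checkVcfHeader(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- .emptyCalls()
    return(out)
  }
  gt <- if (ncol(v@gt) >= 2L) v@gt else NULL
  if (is.null(sampleId))
    sampleId <- if (!is.null(gt)) colnames(gt)[2L]
                else sub("\\.vcf$", "", basename(path))
  fmt <- if (!is.null(gt)) strsplit(gt[, 1L], ":", fixed = TRUE) else NULL
  smp <- if (!is.null(gt)) strsplit(gt[, 2L], ":", fixed = TRUE) else NULL
  getField <- function(i, key) {
    if (is.null(fmt)) return(NA_character_)
    j <- match(key, fmt[[i]])
    if (is.na(j) || j > length(smp[[i]])) NA_character_ else smp[[i]][j]
  }

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    dp <- suppressWarnings(as.integer(getField(i, "DP")))
    ad <- getField(i, "AD")
    adv <- if (!is.na(ad))
      suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1L]]))
      else NA_integer_
    af <- getField(i, "AF")
    afv <- if (!is.na(af))
      suppressWarnings(as.numeric(strsplit(af, ",", fixed = TRUE)[[1L]]))
      else NA_real_
    qual <- suppressWarnings(as.numeric(fix$QUAL[i]))
    sub <- lapply(seq_along(alts), function(k) {
      altDepth <- if (length(adv) >= k + 1L) adv[k + 1L] else NA_integer_
      vaf <- if (!is.na(altDepth) && !is.na(dp) && dp > 0)
        round(100 * altDepth / dp, 4)
      else if (length(afv) >= k && !is.na(afv[k])) round(100 * afv[k], 4)
      else NA_real_
      data.frame(sample_id = sampleId, chrom = fix$CHROM[i],
                 pos = as.integer(fix$POS[i]), ref = fix$REF[i],
                 alt = alts[k], qual = qual,
                 depth = if (is.na(dp)) NA_integer_ else dp,
                 alt_depth = altDepth, vaf_percent = vaf,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  noVaf <- is.na(out$vaf_percent)
  if (any(noVaf))
    warning(sprintf(
      "%d record(s) lack both allele depths and a fraction field; VAF left missing",
      sum(noVaf)), call. = FALSE)
  rownames(out) <- NULL
  out
}

.checkVcfHeader <- function(path) {
  lines <- readLines(path, n = 500L, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], "##fileformat=VCF"))
    stop(sprintf("malformed VCF header in %s at line 1: missing ##fileformat",
                 path), call. = FALSE)
  body <- which(!startsWith(lines, "##"))
  if (length(body) && !startsWith(lines[body[1L]], "#CHROM"))
    stop(sprintf("malformed VCF header in %s at line %d: expected #CHROM line",
                 path, body[1L]), call. = FALSE)
  invisible(TRUE)
}

#' Write per-sample minimal VCF v4.2 files for a cohort
#'
#' One file per sample, carrying `DP` and `AD` FORMAT fields from which the
#' VAF is recoverable. File names are `<sample_id>.vcf`.
#'
#' @param cohort a [VariantCohort-class] (or a calls data.frame)
#' @param dir output directory, created if needed
#' @return invisibly, the written file paths
#' @export
writeCohortVcfs <- function(cohort, dir) {
  calls <- if (is(cohort, "VariantCohort")) cohort@calls else cohort
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in unique(calls$sample_id)) {
    cs <- calls[calls$sample_id == s, , drop = FALSE]
    cs <- cs[order(cs$chrom, cs$pos, cs$alt), , drop = FALSE]
    path <- file.path(dir, paste0(s, ".vcf"))
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=somaticCascade",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", s, sep = "\t"))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\tGT:DP:AD\t0/1:%d:%d,%d",
                    cs$chrom, cs$pos, cs$ref, cs$alt,
                    formatC(cs$qual, format = "g", digits = 8),
                    cs$depth, cs$depth - cs$alt_depth, cs$alt_depth)
    writeLines(c(hdr, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read all per-sample VCFs from a directory
#'
#' @param dir directory containing `*.vcf` files
#' @return combined calls data.frame across samples
#' @export
readVcfDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
  if (!length(files)) return(.emptyCalls())
  out <- do.call(rbind, lapply(files, readVcfCalls))
  rownames(out) <- NULL
  out
}

.writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    x <- out[[j]]
    if (is.logical(x)) x <- ifelse(is.na(x), ".", ifelse(x, "TRUE", "FALSE"))
    else {
      x <- as.character(x)
      x[is.na(x)] <- "."
    }
    out[[j]] <- x
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a variant annotation table
#'
#' Tab-delimited, one row per variant key. Enum columns parse
#' case-insensitively (`"Probably Damaging"` and `"probably_damaging"` are
#' the same level); unknown columns are preserved untouched. Validates the
#' annotation invariants: COSMIC somatic/pathogenic status and a non-empty
#' tissue list both imply COSMIC membership.
#'
#' @param path TSV path with a declared header
#' @return annotations data.frame
#' @export
readAnnotations <- function(path) {
  df <- .readTsv(path)
  if (nrow(df) == 0L) return(.emptyAnnotations())
  for (col in c("in_cosmic", "cosmic_confirmed_somatic", "cosmic_pathogenic",
                "in_icgc", "ensembl_known"))
    df[[col]] <- .asLogicalCol(df[[col]])
  df$sift <- .normEnum(df$sift, "sift")
  df$polyphen <- .normEnum(df$polyphen, "polyphen")
  df$consequence <- .normEnum(df$consequence, "consequence")
  df$pos <- as.integer(df$pos)
  df$population_af <- as.numeric(df$population_af)
  df$cosmic_tissues[is.na(df$cosmic_tissues)] <- ""
  validateAnnotations(df)
  df
}

#' Validate annotation invariants
#'
#' @param ann annotations data.frame
#' @return invisibly TRUE; errors listing offending variant keys otherwise
#' @export
validateAnnotations <- function(ann) {
  if (nrow(ann) == 0L) return(invisible(TRUE))
  keys <- variantKey(ann)
  bad1 <- (ann$cosmic_confirmed_somatic | ann$cosmic_pathogenic) &
    !ann$in_cosmic
  bad2 <- nzchar(ann$cosmic_tissues) & !ann$in_cosmic
  bad <- which(bad1 | bad2)
  if (length(bad))
    stop(sprintf(
      "annotation invariant violated (COSMIC status or tissues without in_cosmic) for: %s",
      paste(keys[bad], collapse = ", ")), call. = FALSE)
  af <- ann$population_af
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("population_af must lie in [0,1]", call. = FALSE)
  invisible(TRUE)
}

#' Read a patient clinicopathological table
#'
#' @param path TSV path
#' @return patients data.frame with normalized enum levels
#' @export
readPatients <- function(path) {
  df <- .readTsv(path)
  if (nrow(df) == 0L) return(.emptyPatients())
  df$gender <- .normEnum(df$gender, "gender")
  df$t_stage <- .normEnum(toupper(df$t_stage), "t_stage")
  df$n_stage <- .normEnum(toupper(df$n_stage), "n_stage")
  df$m_stage <- .normEnum(toupper(df$m_stage), "m_stage")
  df$overall_stage <- .normEnum(toupper(df$overall_stage), "overall_stage")
  df$site <- .normEnum(df$site, "site")
  df$age_years <- as.numeric(df$age_years)
  if (any(!is.na(df$age_years) & df$age_years < 0))
    stop("age_years must be non-negative", call. = FALSE)
  df
}

#' Write annotations, patients or classified variants as TSV
#'
#' Tab-delimited, UTF-8, `.` for missing values.
#'
#' @param x data.frame to write
#' @param path output path
#' @return invisibly, the path
#' @export
writeTable <- function(x, path) .writeTsv(x, path)

#' @rdname writeTable
#' @param records classified-variant data.frame from [classifyVariants()]
#' @export
writeClassified <- function(records, path) .writeTsv(records, path)
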