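#' Write a haplotype dataset as minimal VCF 4.2
#'
#' One contig per locus (`locus_000`, ...; contig lengths in the header),
#' 1-based positions, phased diploid genotypes (`0|1`), missing calls as
#' `.|.`, fixed `REF=A`/`ALT=T` placeholder alleles (the data model is
#' biallelic 0/1).
#'
#' @param dataset a `haplotype_dataset`.
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(dataset, path) {
  n_ind <- nrow(dataset$samples)
  contigs <- sprintf("locus_%03d", seq_along(dataset$loci) - 1L)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=coalabc",
           sprintf("##contig=<ID=%s,length=%d>", contigs,
                   as.integer(dataset$locus_length)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", dataset$samples$individual),
                 collapse = "\t"))
  body <- character(0)
  for (lc in seq_along(dataset$loci)) {
    l <- dataset$loci[[lc]]
    if (length(l$pos) == 0) next
    g <- l$geno
    a <- g[, 2L * seq_len(n_ind) - 1L, drop = FALSE]
    b <- g[, 2L * seq_len(n_ind), drop = FALSE]
    gt <- matrix(paste0(ifelse(is.na(a), ".", a), "|",
                        ifelse(is.na(b), ".", b)),
                 nrow = nrow(g))
    lines <- paste(contigs[lc], l$pos, ".", "A", "T", ".", "PASS", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    body <- c(body, lines)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the population map (sample, population, continent TSV)
#'
#' @param dataset a `haplotype_dataset`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(dataset, path) {
  utils::write.table(
    data.frame(sample = dataset$samples$individual,
               population = dataset$samples$population,
               continent = dataset$samples$continent),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population map TSV
#'
#' @param path TSV with columns `sample`, `population`, `continent`.
#' @return data.frame.
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "population", "continent")
  if (!all(need %in% names(pm))) {
    stop("parse error: popmap must have columns sample, population, continent")
  }
  pm
}

#' Read a minimal VCF 4.2 file into a haplotype dataset
#'
#' Accepts the dialect written by [write_vcf()]: diploid GT first FORMAT
#' field, phased or unphased (`0|1` and `0/1` are both accepted; phase is
#' ignored since the statistics are genotype-based), missing as `.|.` or
#' `./.`. Positions must be 1-based and at least 1. Every sample must be
#' present in the popmap.
#'
#' @param path VCF path.
#' @param popmap popmap data.frame (or path to one).
#' @return a `haplotype_dataset`.
#' @export
read_vcf <- function(path, popmap) {
  if (is.character(popmap)) popmap <- read_popmap(popmap)
  lines <- readLines(path)
  contig_len <- c()
  header_idx <- NA
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "##")) {
      m <- regmatches(ln, regexec("^##contig=<ID=([^,>]+),length=([0-9]+)", ln))[[1]]
      if (length(m) == 3) contig_len[m[2]] <- as.numeric(m[3])
    } else if (startsWith(ln, "#CHROM")) {
      header_idx <- i
      break
    } else {
      stop("parse error at line ", i, ": expected header line")
    }
  }
  if (is.na(header_idx)) stop("parse error: missing #CHROM header line")
  hdr <- strsplit(lines[header_idx], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("parse error: VCF has no sample columns")
  samples <- hdr[-(1:9)]
  missing_pm <- setdiff(samples, popmap$sample)
  if (length(missing_pm) > 0) {
    stop("sample(s) in VCF absent from popmap: ",
         paste(missing_pm, collapse = ", "))
  }
  pm <- popmap[match(samples, popmap$sample), ]
  n_ind <- length(samples)

  if (length(contig_len) == 0) stop("parse error: no ##contig header lines")
  loci_names <- names(contig_len)
  loci <- stats::setNames(
    rep(list(list(pos = integer(0),
                  geno = matrix(integer(0), 0, 2 * n_ind))), length(loci_names)),
    loci_names)
  body <- lines[-seq_len(header_idx)]
  rows <- list()
  for (k in seq_along(body)) {
    line_no <- header_idx + k
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9 + n_ind) {
      stop("parse error at line ", line_no, ": expected ", 9 + n_ind,
           " fields, found ", length(f))
    }
    chrom <- f[1]
    if (!chrom %in% loci_names) {
      stop("parse error at line ", line_no, ": unknown contig ", chrom)
    }
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos) || pos < 1) {
      stop("parse error at line ", line_no,
           ": POS must be a 1-based positive integer")
    }
    gt <- sub(":.*$", "", f[-(1:9)])
    parts <- strsplit(gt, "[|/]")
    bad <- which(vapply(parts, length, integer(1)) != 2)
    if (length(bad) > 0) {
      stop("parse error at line ", line_no, ": malformed GT for sample ",
           samples[bad[1]])
    }
    al <- t(vapply(parts, function(p) {
      v <- suppressWarnings(as.integer(p))
      v[p == "."] <- NA_integer_
      v
    }, integer(2)))
    if (any(al > 1, na.rm = TRUE)) {
      stop("parse error at line ", line_no, ": only biallelic 0/1 supported")
    }
    rows[[length(rows) + 1L]] <- list(chrom = chrom, pos = pos,
                                      hap = as.integer(t(al)))
  }
  for (chrom in loci_names) {
    sel <- Filter(function(r) r$chrom == chrom, rows)
    if (length(sel) == 0) next
    pos <- vapply(sel, `[[`, integer(1), "pos")
    o <- order(pos)
    geno <- do.call(rbind, lapply(sel, `[[`, "hap"))[o, , drop = FALSE]
    loci[[chrom]] <- list(pos = pos[o], geno = geno)
  }
  structure(list(loci = unname(loci),
                 samples = data.frame(individual = samples,
                                      population = pm$population,
                                      continent = pm$continent,
                                      stringsAsFactors = FALSE),
                 locus_length = unname(contig_len[1]),
                 masks = NULL, trees = NULL),
            class = "haplotype_dataset")
}

#' Write mask tracks as BED
#'
#' 0-based half-open intervals, one row per masked span, fourth column =
#' individual id. Contig names match the VCF (`locus_000`, ...).
#'
#' @param dataset a masked `haplotype_dataset`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_bed_mask <- function(dataset, path) {
  if (is.null(dataset$masks)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rows <- character(0)
  for (i in seq_len(nrow(dataset$samples))) {
    for (lc in seq_along(dataset$masks[[i]])) {
      iv <- dataset$masks[[i]][[lc]]
      if (nrow(iv) == 0) next
      rows <- c(rows, sprintf("locus_%03d\t%d\t%d\t%s", lc - 1L,
                              as.integer(iv[, 1]), as.integer(iv[, 2]),
                              dataset$samples$individual[i]))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read mask tracks from BED into a dataset
#'
#' @param path BED path (chrom, start, end, individual).
#' @param dataset the `haplotype_dataset` the masks belong to.
#' @return the dataset with `masks` attached (genotypes are not re-masked;
#'   use [apply_mask()] to generate missingness).
#' @export
read_bed_mask <- function(path, dataset) {
  n_loci <- length(dataset$loci)
  n_ind <- nrow(dataset$samples)
  masks <- rep(list(rep(list(matrix(numeric(0), 0, 2)), n_loci)), n_ind)
  lines <- readLines(path)
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4) stop("parse error at line ", k, ": expected 4 BED fields")
    lc <- match(f[1], sprintf("locus_%03d", seq_len(n_loci) - 1L))
    ind <- match(f[4], dataset$samples$individual)
    if (is.na(lc) || is.na(ind)) {
      stop("parse error at line ", k, ": unknown contig or individual")
    }
    masks[[ind]][[lc]] <- rbind(masks[[ind]][[lc]],
                                as.numeric(f[2:3]))
  }
  dataset$masks <- lapply(masks, function(m) lapply(m, merge_intervals))
  dataset
}
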