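# Readers and writers for PLINK-style text genotypes (.ped/.map and the
# transposed .tped/.tfam dialect), tab-delimited expression matrices, and the
# pruned results TSV. All downstream modules consume only the in-memory
# genotype_matrix / expression_matrix containers built here.

read_whitespace_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1]])
}

# Code one SNP's allele pairs as minor-allele counts. a1, a2: character
# vectors of length N. Minor designation: the allele with frequency <= 0.5
# among non-missing calls; at an exact 0.5 tie the lexicographically smaller
# character is major.
code_alleles <- function(a1, a2, snp_id) {
  miss <- a1 %in% MISSING_ALLELES | a2 %in% MISSING_ALLELES
  obs <- c(a1[!miss], a2[!miss])
  alleles <- sort(unique(obs), method = "radix")
  if (length(alleles) > 2) {
    stop("SNP '", snp_id, "' has >2 distinct non-missing alleles: ",
         paste(alleles, collapse = ", "))
  }
  if (length(alleles) == 0) {
    return(list(calls = rep(NA_integer_, length(a1)),
                major = NA_character_, minor = NA_character_))
  }
  if (length(alleles) == 1) {
    calls <- rep(0L, length(a1))
    calls[miss] <- NA_integer_
    return(list(calls = calls, major = alleles, minor = NA_character_))
  }
  n1 <- sum(obs == alleles[1])
  n2 <- sum(obs == alleles[2])
  # tie (each exactly half): smaller character (alleles[1]) is major
  if (n1 >= n2) {
    major <- alleles[1]; minor <- alleles[2]
  } else {
    major <- alleles[2]; minor <- alleles[1]
  }
  calls <- (a1 == minor) + (a2 == minor)
  calls[miss] <- NA_integer_
  list(calls = as.integer(calls), major = major, minor = minor)
}

parse_map <- function(map_path, n_cols = 4L) {
  rows <- read_whitespace_lines(map_path)
  bad <- which(vapply(rows, length, 1L) != n_cols)
  if (length(bad)) {
    stop("map/tfam file '", map_path, "' line ", bad[1], ": expected ",
         n_cols, " fields, got ", length(rows[[bad[1]]]))
  }
  data.frame(
    chrom = vapply(rows, `[`, "", 1L),
    snp_id = vapply(rows, `[`, "", 2L),
    pos = as.integer(vapply(rows, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Read genotypes from PLINK text .ped/.map files
#'
#' Parses the sample-major PLINK text dialect: each `.ped` row carries six
#' metadata columns (family, individual, paternal, maternal, sex, phenotype)
#' followed by two allele characters per SNP; the `.map` file lists
#' chromosome, SNP id, genetic distance, and 1-based position, one SNP per
#' row. Allele characters `"0"` and `"N"` mark missing calls; a sample with
#' at least one missing allele at a SNP is missing for that SNP. Calls are
#' coded as minor-allele copy counts, the minor allele being the one with
#' frequency at most 0.5 among non-missing calls (exact ties resolved by
#' making the lexicographically smaller character the major allele).
#'
#' @param ped_path path to the `.ped` file.
#' @param map_path path to the `.map` file.
#' @return A [genotype_matrix]. Sample ids are taken from the individual-id
#'   column of the `.ped` file.
#' @seealso [read_genotypes_tped()] for the transposed dialect.
#' @export
read_genotypes_ped <- function(ped_path, map_path) {
  map <- parse_map(map_path)
  s <- nrow(map)
  rows <- read_whitespace_lines(ped_path)
  expected <- 6L + 2L * s
  widths <- vapply(rows, length, 1L)
  bad <- which(widths != expected)
  if (length(bad)) {
    stop("ped file '", ped_path, "' line ", bad[1], ": expected ", expected,
         " fields for ", s, " SNPs in '", map_path, "', got ", widths[bad[1]])
  }
  n <- length(rows)
  sample_ids <- vapply(rows, `[`, "", 2L)
  calls <- matrix(NA_integer_, nrow = s, ncol = n)
  major <- minor <- rep(NA_character_, s)
  if (n > 0 && s > 0) {
    allele_mat <- do.call(rbind, lapply(rows, function(r) r[-(1:6)]))
    for (k in seq_len(s)) {
      coded <- code_alleles(allele_mat[, 2L * k - 1L], allele_mat[, 2L * k],
                            map$snp_id[k])
      calls[k, ] <- coded$calls
      major[k] <- coded$major
      minor[k] <- coded$minor
    }
  }
  genotype_matrix(
    calls,
    data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
               major = major, minor = minor, stringsAsFactors = FALSE),
    sample_ids
  )
}

#' Read genotypes from PLINK text .tped/.tfam files
#'
#' The transposed dialect: each `.tped` row is one SNP (chromosome, SNP id,
#' genetic distance, position, then two allele characters per sample); the
#' `.tfam` file lists the six sample-metadata columns, one sample per row.
#' Missing-allele and minor-allele conventions are identical to
#' [read_genotypes_ped()]; the two readers produce identical containers for
#' the same cohort.
#'
#' @param tped_path path to the `.tped` file.
#' @param tfam_path path to the `.tfam` file.
#' @return A [genotype_matrix].
#' @export
read_genotypes_tped <- function(tped_path, tfam_path) {
  fam <- read_whitespace_lines(tfam_path)
  bad <- which(vapply(fam, length, 1L) != 6L)
  if (length(bad)) {
    stop("tfam file '", tfam_path, "' line ", bad[1],
         ": expected 6 fields, got ", length(fam[[bad[1]]]))
  }
  sample_ids <- vapply(fam, `[`, "", 2L)
  n <- length(sample_ids)
  rows <- read_whitespace_lines(tped_path)
  s <- length(rows)
  expected <- 4L + 2L * n
  calls <- matrix(NA_integer_, nrow = s, ncol = n)
  info <- data.frame(snp_id = character(s), chrom = character(s),
                     pos = integer(s), major = rep(NA_character_, s),
                     minor = rep(NA_character_, s), stringsAsFactors = FALSE)
  for (k in seq_len(s)) {
    r <- rows[[k]]
    if (length(r) != expected) {
      stop("tped file '", tped_path, "' line ", k, ": expected ", expected,
           " fields for ", n, " samples in '", tfam_path, "', got ", length(r))
    }
    al <- r[-(1:4)]
    coded <- code_alleles(al[seq(1L, 2L * n, by = 2L)],
                          al[seq(2L, 2L * n, by = 2L)], r[2])
    calls[k, ] <- coded$calls
    info$snp_id[k] <- r[2]
    info$chrom[k] <- r[1]
    info$pos[k] <- as.integer(r[4])
    info$major[k] <- coded$major
    info$minor[k] <- coded$minor
  }
  genotype_matrix(calls, info, sample_ids)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of probe ids; every
#' remaining cell must parse as a number. There is no silent imputation: a
#' non-numeric cell (including literal `"NA"`) is a parse error naming the
#' offending probe and sample.
#'
#' @param path path to the tab-delimited expression file.
#' @return An [expression_matrix] with probes in file order.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           row.names = NULL, quote = "")
  if (ncol(raw) < 2) stop("expression file '", path, "' has no sample columns")
  probe_ids <- raw[[1]]
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe id in '", path, "': ",
         probe_ids[duplicated(probe_ids)][1])
  }
  sample_ids <- colnames(raw)[-1]
  values <- matrix(NA_real_, nrow = nrow(raw), ncol = length(sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad)) {
      stop("expression file '", path, "': non-numeric cell \"", col[bad[1]],
           "\" at probe '", probe_ids[bad[1]], "', sample '",
           sample_ids[j], "'")
    }
    values[, j] <- num
  }
  expression_matrix(values, probe_ids, sample_ids)
}

#' Restrict genotype and expression matrices to their common samples
#'
#' Both matrices are subset to the intersection of their sample ids and put
#' in the same column order (order of first appearance in the genotype
#' matrix). Sample alignment is a prerequisite of every scan.
#'
#' @param g a [genotype_matrix].
#' @param e an [expression_matrix].
#' @return A list with elements `genotypes` and `expression`, both restricted
#'   to the shared samples in identical order.
#' @export
align_samples <- function(g, e) {
  common <- g$sample_ids[g$sample_ids %in% e$sample_ids]
  if (length(common) == 0) {
    stop("no samples shared between genotype and expression data")
  }
  gi <- match(common, g$sample_ids)
  ei <- match(common, e$sample_ids)
  g2 <- genotype_matrix(g$calls[, gi, drop = FALSE], g$snp_info, common)
  e2 <- expression_matrix(e$values[, ei, drop = FALSE], e$probe_ids, common)
  list(genotypes = g2, expression = e2)
}

#' Write pruned scan results as TSV
#'
#' Emits one row per trio with `p <= threshold`, with p-values in scientific
#' notation at 6+ significant digits so thresholds at the 1e-14 scale remain
#' exactly representable in the text output.
#'
#' @param results data frame of trio results (columns `snp`, `probe_i`,
#'   `probe_j`, `r1`, `r2`, `m1`, `m2`, `Z`, `p`), e.g. the `results`
#'   element of [run_scan()].
#' @param path output file path.
#' @param threshold p-value threshold in (0, 1]; only trios at or below it
#'   are written.
#' @return The number of records written, invisibly.
#' @export
write_results <- function(results, path, threshold = 1) {
  stopifnot(is.numeric(threshold), threshold > 0, threshold <= 1)
  keep <- results[results$p <= threshold, , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  header <- c("snp", "probe_i", "probe_j", "r1", "r2", "m1", "m2", "Z", "p")
  writeLines(paste(header, collapse = "\t"), con)
  if (nrow(keep)) {
    lines <- sprintf("%s\t%s\t%s\t%.8f\t%.8f\t%d\t%d\t%.6f\t%.6e",
                     keep$snp, keep$probe_i, keep$probe_j, keep$r1, keep$r2,
                     as.integer(keep$m1), as.integer(keep$m2), keep$Z, keep$p)
    writeLines(lines, con)
  }
  invisible(nrow(keep))
}

#' Write genotypes to PLINK text .ped/.map files
#'
#' Inverse of [read_genotypes_ped()]: calls are expanded back to allele
#' pairs (0 -> major/major, 1 -> major/minor, 2 -> minor/minor, missing ->
#' `0 0`). Family/paternal/maternal/sex/phenotype metadata columns are
#' filled with placeholder values.
#'
#' @param g a [genotype_matrix].
#' @param ped_path,map_path output paths.
#' @return The input `g`, invisibly.
#' @export
write_genotypes_ped <- function(g, ped_path, map_path) {
  info <- g$snp_info
  writeLines(sprintf("%s\t%s\t0\t%d", info$chrom, info$snp_id, info$pos),
             map_path)
  n <- ncol(g$calls)
  lines <- character(n)
  for (j in seq_len(n)) {
    pairs <- call_to_alleles(g$calls[, j], info$major, info$minor)
    lines[j] <- paste(c(g$sample_ids[j], g$sample_ids[j], "0", "0", "0", "-9",
                        pairs), collapse = "\t")
  }
  writeLines(lines, ped_path)
  invisible(g)
}

#' Write genotypes to PLINK text .tped/.tfam files
#'
#' Transposed-dialect counterpart of [write_genotypes_ped()].
#'
#' @param g a [genotype_matrix].
#' @param tped_path,tfam_path output paths.
#' @return The input `g`, invisibly.
#' @export
write_genotypes_tped <- function(g, tped_path, tfam_path) {
  writeLines(sprintf("%s\t%s\t0\t0\t0\t-9", g$sample_ids, g$sample_ids),
             tfam_path)
  info <- g$snp_info
  s <- nrow(g$calls)
  lines <- character(s)
  for (k in seq_len(s)) {
    pairs <- call_to_alleles(g$calls[k, ], info$major[k], info$minor[k])
    lines[k] <- paste(c(info$chrom[k], info$snp_id[k], "0", info$pos[k],
                        pairs), collapse = "\t")
  }
  writeLines(lines, tped_path)
  invisible(g)
}

# Expand minor-allele counts to interleaved "a1 a2" strings.
call_to_alleles <- function(calls, major, minor) {
  a1 <- ifelse(is.na(calls), "0", ifelse(calls == 2L, minor, major))
  a2 <- ifelse(is.na(calls), "0", ifelse(calls >= 1L, minor, major))
  paste(a1, a2, sep = "\t")
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression()]: header row of sample ids, first column of
#' probe ids.
#'
#' @param e an [expression_matrix].
#' @param path output path.
#' @return The input `e`, invisibly.
#' @export
write_expression <- function(e, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("probe_id", e$sample_ids), collapse = "\t"), con)
  body <- apply(e$values, 1, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(e$probe_ids, body, sep = "\t"), con)
  invisible(e)
}
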