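#' Write genotypes as PLINK text (.ped/.map)
#'
#' One line per individual in the .ped file (family id, individual id,
#' father, mother, sex, phenotype, then two allele columns per SNP; missing
#' calls written as `0 0`), and one line per SNP in the .map file
#' (chromosome, SNP id, genetic distance 0, base-pair position).
#'
#' @param geno A `geno_matrix`.
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(geno, prefix) {
  stopifnot(inherits(geno, "geno_matrix"))
  calls <- geno$calls
  map <- geno$map
  m <- ncol(calls)
  a_counted <- map$counted_allele
  a_other <- ifelse(map$counted_allele == map$allele2, map$allele1, map$allele2)

  ped_lines <- vapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    al1 <- ifelse(is.na(x), "0", ifelse(x >= 1, a_counted, a_other))
    al2 <- ifelse(is.na(x), "0", ifelse(x == 2, a_counted, a_other))
    paste(c("FAM1", rownames(calls)[i], "0", "0", "0", "-9",
            as.vector(rbind(al1, al2))), collapse = " ")
  }, character(1))
  writeLines(ped_lines, paste0(prefix, ".ped"))

  map_lines <- paste(map$chrom, map$snp, 0,
                     ifelse(is.na(map$pos), 0, map$pos))
  writeLines(map_lines, paste0(prefix, ".map"))
  invisible(prefix)
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the two-allele-column text format back into a dosage matrix.  The
#' counted allele at each SNP is the allele with the greater observed
#' frequency (ties broken alphabetically), recorded in the map.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @return A `geno_matrix`.
#' @export
read_plink <- function(prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  if (!file.exists(ped_path) || !file.exists(map_path)) {
    abort(paste0("missing .ped/.map pair at prefix ", prefix),
          class = "reactnorm_io_error")
  }
  map_raw <- utils::read.table(map_path, header = FALSE,
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
  names(map_raw) <- c("chrom", "snp", "cm", "pos")
  m <- nrow(map_raw)

  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  if (ncol(ped) != 6 + 2 * m) {
    abort(".ped column count does not match the .map SNP count.",
          class = "reactnorm_io_error")
  }
  n <- nrow(ped)
  ids <- ped[[2]]
  al1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  al2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])

  calls <- matrix(NA_integer_, n, m, dimnames = list(ids, map_raw$snp))
  allele1 <- allele2 <- counted <- character(m)
  for (k in seq_len(m)) {
    a <- al1[, k]; b <- al2[, k]
    obs <- c(a[a != "0"], b[b != "0"])
    alleles <- sort(unique(obs))
    if (length(alleles) == 0) alleles <- c("A", "B")
    if (length(alleles) == 1) alleles <- c(alleles, setdiff(c("A", "B"), alleles)[1])
    if (length(alleles) > 2) {
      abort(paste0("SNP ", map_raw$snp[k], " has more than two alleles."),
            class = "reactnorm_io_error")
    }
    counts <- vapply(alleles, function(al) sum(obs == al), integer(1))
    cnt <- alleles[which.max(counts)]  # ties: first alphabetically
    ok <- a != "0" & b != "0"
    calls[ok, k] <- (a[ok] == cnt) + (b[ok] == cnt)
    allele1[k] <- alleles[1]; allele2[k] <- alleles[2]; counted[k] <- cnt
  }
  map <- tibble(
    snp = map_raw$snp, chrom = map_raw$chrom,
    pos = ifelse(map_raw$pos > 0, map_raw$pos, NA_integer_),
    allele1 = allele1, allele2 = allele2, counted_allele = counted
  )
  new_geno_matrix(calls, map)
}
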