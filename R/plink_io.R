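# PLINK-dialect ped/map text I/O for matched pen-mate pairs.
#
# Genotypes are held as one-letter codes: A/C/G/T for homozygotes, the
# IUPAC ambiguity letter for heterozygotes (R = A/G, Y = C/T, M = A/C,
# K = G/T, S = C/G, W = A/T) and "N" for missing.

#' Missing-genotype token
#'
#' The single reserved one-letter code used for a missing genotype call,
#' distinct from every IUPAC nucleotide letter.
#' @return A length-one character vector.
#' @export
missing_call <- function() "N"

# unordered allele pair -> IUPAC ambiguity letter
.iupac_table <- c(
  "AG" = "R", "CT" = "Y", "AC" = "M", "GT" = "K", "CG" = "S", "AT" = "W"
)

#' IUPAC ambiguity code for an unordered allele pair
#'
#' @param a1,a2 Single nucleotide letters in \code{A,C,G,T}; must differ.
#' @return The one-letter ambiguity code (e.g. \code{"R"} for A/G).
#' @export
iupac_het <- function(a1, a2) {
  key <- paste0(pmin(a1, a2), pmax(a1, a2))
  code <- .iupac_table[key]
  if (anyNA(code)) {
    stop("no IUPAC code for allele pair(s): ", paste(key[is.na(code)], collapse = ", "))
  }
  unname(code)
}

#' Expand a one-letter genotype code to its two alleles
#'
#' Inverse of the one-letter encoding: homozygous letters repeat, the
#' ambiguity letter splits into its two alleles in alphabetical order,
#' and the missing token becomes \code{"0", "0"}.
#'
#' @param code One-letter genotype code.
#' @return Character vector of length 2.
#' @export
expand_call <- function(code) {
  if (code == missing_call()) return(c("0", "0"))
  if (code %in% c("A", "C", "G", "T")) return(c(code, code))
  hit <- names(.iupac_table)[.iupac_table == code]
  if (length(hit) != 1L) stop("unknown genotype code: ", code)
  c(substr(hit, 1, 1), substr(hit, 2, 2))
}

# chromosome label -> internal integer code (0 unmapped, 1..29 autosomes,
# 30 = X, 31 = Y, 32 = MT)
normalize_chrom <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- suppressWarnings(as.integer(x))
  out[x == "X"] <- 30L
  out[x == "Y"] <- 31L
  out[x %in% c("MT", "M")] <- 32L
  bad <- is.na(out) | out < 0L | out > 32L
  if (any(bad)) {
    stop("unrecognized chromosome label(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Read a PLINK map file
#'
#' Each line holds four whitespace-delimited fields: chromosome, SNP id,
#' genetic distance (kept but unused) and 1-based physical position.
#' Chromosome labels are normalized to integer codes 0-32 with X = 30,
#' Y = 31, MT = 32.
#'
#' @param path Path to the map text file.
#' @return A data.frame with columns \code{chrom}, \code{snp_id},
#'   \code{cm}, \code{pos_bp}, in file order.
#' @export
read_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(chrom = integer(), snp_id = character(),
                      cm = numeric(), pos_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    stop("malformed map line(s) (need 4 fields): line ",
         paste(which(nf != 4L), collapse = ", "))
  }
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 4]))
  if (anyNA(pos)) {
    stop("non-numeric position on map line ", which(is.na(pos))[1])
  }
  snps <- data.frame(
    chrom = normalize_chrom(m[, 1]),
    snp_id = m[, 2],
    cm = suppressWarnings(as.numeric(m[, 3])),
    pos_bp = pos,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(snps$snp_id)) {
    warning("duplicate snp_id(s) in map: ",
            paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  snps
}

#' Construct a paired genotype matrix
#'
#' Low-level constructor for the container used throughout the package:
#' one row per animal (2N, control listed first within each pair), one
#' column per SNP, one-letter genotype codes.
#'
#' @param animals data.frame with columns \code{pair}, \code{iid},
#'   \code{pat}, \code{mat}, \code{sex}, \code{phenotype} (1 = control,
#'   2 = case).
#' @param snps data.frame as returned by \code{\link{read_map}}, plus
#'   allele columns \code{a1} (major) and \code{a2} (minor).
#' @param calls Character matrix, \code{nrow(animals)} x \code{nrow(snps)}.
#' @return An object of class \code{paired_genotypes}.
#' @export
paired_genotypes <- function(animals, snps, calls) {
  stopifnot(is.data.frame(animals), is.data.frame(snps), is.matrix(calls))
  stopifnot(nrow(calls) == nrow(animals), ncol(calls) == nrow(snps))
  rownames(calls) <- animals$iid
  colnames(calls) <- snps$snp_id
  obj <- structure(
    list(animals = animals, snps = snps, calls = calls),
    class = "paired_genotypes"
  )
  validate_paired_genotypes(obj)
  obj
}

#' Validate the pair structure of a genotype matrix
#'
#' Checks that every pair has exactly one control (phenotype 1) and one
#' case (phenotype 2), the control ordered first, and that all calls are
#' legal one-letter codes.
#'
#' @param x A \code{paired_genotypes} object.
#' @return \code{x}, invisibly; errors on violation.
#' @export
validate_paired_genotypes <- function(x) {
  an <- x$animals
  tab <- split(an$phenotype, an$pair)
  bad <- names(tab)[!vapply(tab, function(p) {
    length(p) == 2L && setequal(p, c(1, 2))
  }, logical(1))]
  if (length(bad)) {
    stop("pair(s) without exactly one control and one case: ",
         paste(bad, collapse = ", "))
  }
  first <- an$phenotype[!duplicated(an$pair)]
  if (any(first != 1)) {
    stop("control (phenotype 1) must be listed first within each pair")
  }
  legal <- c("A", "C", "G", "T", unname(.iupac_table), missing_call())
  if (!all(x$calls %in% legal)) {
    stop("illegal genotype code(s): ",
         paste(unique(x$calls[!(x$calls %in% legal)]), collapse = ", "))
  }
  invisible(x)
}

#' @export
print.paired_genotypes <- function(x, ...) {
  cat("paired_genotypes:", n_pairs(x), "pairs x", nrow(x$snps), "SNPs\n")
  invisible(x)
}

#' Number of case-control pairs
#' @param x A \code{paired_genotypes} object.
#' @return Integer pair count.
#' @export
n_pairs <- function(x) length(unique(x$animals$pair))

# row indices of controls and cases, aligned by pair order of appearance
pair_rows <- function(x) {
  an <- x$animals
  ord <- unique(an$pair)
  ctrl <- match(paste(ord, 1), paste(an$pair, an$phenotype))
  case <- match(paste(ord, 2), paste(an$pair, an$phenotype))
  list(pairs = ord, control = ctrl, case = case)
}

#' Genotype dosage of the a1 allele
#'
#' Converts one-letter calls to counts of the a1 allele (0, 1, 2), with
#' \code{NA} for missing. Used internally by the scan and IBS code.
#'
#' @param x A \code{paired_genotypes} object.
#' @return Integer matrix, animals x SNPs.
#' @export
dosage_a1 <- function(x) {
  d <- matrix(NA_integer_, nrow(x$calls), ncol(x$calls),
              dimnames = dimnames(x$calls))
  a1 <- x$snps$a1
  a2 <- x$snps$a2
  het <- iupac_het(a1, a2)
  for (j in seq_len(ncol(d))) {
    cj <- x$calls[, j]
    d[cj == a1[j], j] <- 2L
    d[cj == het[j], j] <- 1L
    d[cj == a2[j], j] <- 0L
  }
  d
}

# assign a1 (most frequent allele) / a2 per SNP from two-letter allele
# matrices; ties broken alphabetically
assign_major_minor <- function(al1, al2) {
  M <- ncol(al1)
  a1 <- a2 <- character(M)
  for (j in seq_len(M)) {
    obs <- c(al1[, j], al2[, j])
    obs <- obs[obs != "0"]
    if (length(obs) == 0L) {
      a1[j] <- "A"; a2[j] <- "C"   # placeholder for an all-missing SNP
      next
    }
    tab <- table(obs)
    if (length(tab) > 2L) {
      stop("more than two alleles observed at SNP column ", j, ": ",
           paste(names(tab), collapse = ", "))
    }
    if (length(tab) == 1L) {
      a1[j] <- names(tab)
      a2[j] <- setdiff(c("A", "C", "G", "T"), a1[j])[1]
    } else {
      # most frequent first; alphabetical on ties (deterministic)
      ord <- order(-as.integer(tab), names(tab))
      a1[j] <- names(tab)[ord[1]]
      a2[j] <- names(tab)[ord[2]]
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Read a PLINK ped file into a paired genotype matrix
#'
#' Expects the pair identifier in the family-ID (first) column, six
#' leading columns (FID IID PAT MAT SEX PHENO) and two allele letters
#' per SNP. Phenotype 1 marks the control and 2 the case of each pair.
#' Two-letter genotypes are collapsed to one-letter codes; "0" alleles
#' (including half-missing genotypes) become the missing token. The
#' major allele a1 is the most frequent allele over all typed animals,
#' ties broken alphabetically.
#'
#' @param path Path to the ped text file.
#' @param snps SNP table from \code{\link{read_map}}.
#' @return A \code{paired_genotypes} object with controls ordered first
#'   within each pair.
#' @export
read_ped <- function(path, snps) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  M <- nrow(snps)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 6L + 2L * M)) {
    stop("ped line(s) with wrong field count (expected ", 6L + 2L * M,
         "): line ", paste(which(nf != 6L + 2L * M), collapse = ", "))
  }
  ped <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  animals <- data.frame(
    pair = ped[, 1], iid = ped[, 2], pat = ped[, 3], mat = ped[, 4],
    sex = as.integer(ped[, 5]), phenotype = as.integer(ped[, 6]),
    stringsAsFactors = FALSE
  )
  tab <- split(animals$phenotype, animals$pair)
  bad <- names(tab)[!vapply(tab, function(p) {
    length(p) == 2L && setequal(p, c(1, 2))
  }, logical(1))]
  if (length(bad)) {
    stop("pair(s) without exactly one control and one case: ",
         paste(bad, collapse = ", "))
  }
  geno <- ped[, -(1:6), drop = FALSE]
  al1 <- geno[, seq(1, by = 2, length.out = M), drop = FALSE]
  al2 <- geno[, seq(2, by = 2, length.out = M), drop = FALSE]
  legal <- c("A", "C", "G", "T", "0")
  if (!all(al1 %in% legal) || !all(al2 %in% legal)) {
    offending <- setdiff(unique(c(al1, al2)), legal)
    stop("allele letter(s) outside {A,C,G,T,0}: ",
         paste(offending, collapse = ", "))
  }
  # half-genotypes ("A 0") are treated as fully missing
  half <- (al1 == "0") != (al2 == "0")
  al1[half] <- "0"
  al2[half] <- "0"
  mm <- assign_major_minor(al1, al2)
  calls <- matrix(missing_call(), nrow(al1), M)
  hom <- al1 == al2 & al1 != "0"
  calls[hom] <- al1[hom]
  het <- al1 != al2 & al1 != "0" & al2 != "0"
  if (any(het)) {
    calls[het] <- iupac_het(pmin(al1[het], al2[het]), pmax(al1[het], al2[het]))
  }
  snps$a1 <- mm$a1
  snps$a2 <- mm$a2
  # order: pairs in order of first appearance, control before case
  ord <- order(match(animals$pair, unique(animals$pair)), animals$phenotype)
  paired_genotypes(animals[ord, , drop = FALSE], snps,
                   calls[ord, , drop = FALSE])
}

#' Write ped/map text files
#'
#' Emits PLINK-dialect whitespace-delimited files such that
#' \code{read_ped(read_map())} round-trips the matrix bit-identically on
#' calls, phenotypes and pair structure. Heterozygous one-letter codes
#' expand to their two alleles in alphabetical order; missing becomes
#' \code{0 0}.
#'
#' @param x A \code{paired_genotypes} object.
#' @param prefix Output path prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}.
#' @return The two file paths, invisibly.
#' @export
write_ped_map <- function(x, prefix) {
  validate_paired_genotypes(x)
  snps <- x$snps
  chrom_out <- as.character(snps$chrom)
  map_lines <- paste(chrom_out, snps$snp_id,
                     ifelse(is.na(snps$cm), 0, snps$cm), snps$pos_bp)
  writeLines(map_lines, paste0(prefix, ".map"))
  an <- x$animals
  M <- nrow(snps)
  geno_txt <- character(nrow(an))
  if (M > 0L) {
    expanded <- apply(x$calls, c(1, 2), function(code) {
      paste(expand_call(code), collapse = " ")
    })
    geno_txt <- apply(expanded, 1, paste, collapse = " ")
    ped_lines <- paste(an$pair, an$iid, an$pat, an$mat, an$sex,
                       an$phenotype, geno_txt)
  } else {
    ped_lines <- paste(an$pair, an$iid, an$pat, an$mat, an$sex, an$phenotype)
  }
  writeLines(ped_lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}
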