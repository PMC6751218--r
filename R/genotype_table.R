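# Genotype tables: variants x samples dosage/depth matrices plus a registry
# of monomorphic (invariant but sequenced) sites. Coordinates are 1-based
# inclusive, VCF-style, throughout.

#' Construct a genotype table
#'
#' A `geno_table` bundles the two site classes a reduced-representation
#' dataset carries: polymorphic variants (with per-sample allele dosages and
#' read depths) and monomorphic sequenced sites, which later stages need for
#' SFS normalisation and window building.
#'
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `rad_locus_id`; one row per variant, sorted by (chrom, pos).
#' @param geno integer matrix (variants x samples) of alt-allele dosages in
#'   \{0, 1, 2\}, `NA` for missing.
#' @param depth integer matrix of per-genotype read depths (same shape).
#' @param samples character vector of sample ids (column order of `geno`).
#' @param monomorphic data.frame with columns `chrom`, `pos` and optionally
#'   `rad_locus_id`: invariant sequenced sites.
#' @param ad_ref,ad_alt optional integer matrices of per-genotype allelic
#'   depths (reference / alternate reads).
#' @return An object of class `geno_table`.
#' @export
geno_table <- function(variants, geno, depth, samples,
                       monomorphic = empty_monomorphic(),
                       ad_ref = NULL, ad_alt = NULL) {
  variants <- as.data.frame(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (is.null(variants$rad_locus_id))
    variants$rad_locus_id <- assign_rad_loci(variants$chrom, variants$pos)
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  if (nrow(variants) != nrow(geno) || nrow(variants) != nrow(depth))
    stop("variants, geno and depth must have one row per variant")
  if (ncol(geno) != length(samples))
    stop("geno must have one column per sample")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos) in variants")
  mono <- as.data.frame(monomorphic)
  if (nrow(mono) > 0) {
    mkey <- paste(mono$chrom, mono$pos)
    if (any(mkey %in% key))
      stop("monomorphic sites overlap variant positions")
    mono <- mono[order(mono$chrom, mono$pos), , drop = FALSE]
    rownames(mono) <- NULL
  }
  o <- order(variants$chrom, variants$pos)
  variants <- variants[o, , drop = FALSE]
  rownames(variants) <- NULL
  geno <- geno[o, , drop = FALSE]
  depth <- depth[o, , drop = FALSE]
  if (!is.null(ad_ref)) ad_ref <- as.matrix(ad_ref)[o, , drop = FALSE]
  if (!is.null(ad_alt)) ad_alt <- as.matrix(ad_alt)[o, , drop = FALSE]
  dimnames(geno) <- dimnames(depth) <- list(NULL, samples)
  structure(list(variants = variants, geno = geno, depth = depth,
                 samples = as.character(samples), monomorphic = mono,
                 ad_ref = ad_ref, ad_alt = ad_alt),
            class = "geno_table")
}

empty_monomorphic <- function() {
  data.frame(chrom = character(), pos = integer())
}

#' @export
print.geno_table <- function(x, ...) {
  cat(sprintf("geno_table: %d variants, %d samples, %d monomorphic sites\n",
              nrow(x$variants), length(x$samples), nrow(x$monomorphic)))
  invisible(x)
}

#' Number of sequenced sites (variant + monomorphic)
#' @param x a `geno_table`
#' @export
n_sites <- function(x) nrow(x$variants) + nrow(x$monomorphic)

# Group sites into RAD loci by proximity: a new locus starts whenever the gap
# to the previous site exceeds `gap` or the chromosome changes.
assign_rad_loci <- function(chrom, pos, gap = 200L) {
  if (length(pos) == 0) return(integer(0))
  o <- order(chrom, pos)
  newlocus <- c(TRUE, chrom[o][-1] != chrom[o][-length(o)] |
                  diff(pos[o]) > gap)
  id <- cumsum(newlocus)
  out <- integer(length(pos))
  out[o] <- id
  out
}

#' Read a population map
#'
#' Two whitespace-separated columns: sample id, population label.
#'
#' @param path file path
#' @return data.frame with columns `sample` and `pop`
#' @export
read_popmap <- function(path) {
  pm <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(pm) < 2) stop("popmap must have two columns: sample, population")
  data.frame(sample = as.character(pm[[1]]), pop = as.character(pm[[2]]),
             stringsAsFactors = FALSE)
}

# Every sample of the table must carry exactly one label.
check_popmap <- function(table, popmap) {
  if (anyDuplicated(popmap$sample)) {
    dup <- popmap$sample[duplicated(popmap$sample)][1]
    stop("sample '", dup, "' has more than one population label")
  }
  missing <- setdiff(table$samples, popmap$sample)
  if (length(missing) > 0)
    stop("samples without population label: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

pops_of <- function(table, popmap) {
  popmap$pop[match(table$samples, popmap$sample)]
}

#' Read a VCF file (and optionally a popmap) into a genotype table
#'
#' Dosages come from the `GT` FORMAT field, depths from `DP` and allelic
#' depths from `AD` when present. Records with a missing/`.` ALT allele are
#' routed to the monomorphic-site registry; multiallelic and indel records
#' are retained as read and removed later by [filter_biallelic_autosomal()].
#' A `RAD=<id>` INFO tag, when present, defines RAD-locus membership;
#' otherwise loci are inferred from site proximity.
#'
#' @param path VCF file (v4.x, plain text or gzipped)
#' @param popmap_path optional two-column popmap; every sample named there
#'   must exist in the VCF
#' @return a `geno_table`, or `list(table, popmap)` when `popmap_path` is
#'   given
#' @export
read_vcf <- function(path, popmap_path = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  chrom <- fix$CHROM
  pos <- as.integer(fix$POS)
  alt <- fix$ALT
  ref <- fix$REF
  info <- fix$INFO
  rad <- rep(NA_character_, length(info))
  has_rad <- !is.na(info) & grepl("(^|;)RAD=", info)
  rad[has_rad] <- sub(".*RAD=([^;]+).*", "\\1", info[has_rad])
  invariant <- is.na(alt) | alt == "." | alt == ""

  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  samples <- colnames(gt)
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  dp[is.na(dp)] <- 0

  dos <- gt_to_dosage(gt)
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad) && any(!is.na(ad))) {
    ad_ref <- matrix(suppressWarnings(
      as.integer(sub(",.*", "", ad))), nrow(ad), ncol(ad))
    ad_alt <- matrix(suppressWarnings(
      as.integer(sub("^[^,]*,", "", sub("(,[^,]*),.*", "\\1", ad)))),
      nrow(ad), ncol(ad))
  }

  rad_all <- rad
  if (all(is.na(rad_all))) rad_all <- assign_rad_loci(chrom, pos)
  mono <- data.frame(chrom = chrom[invariant], pos = pos[invariant],
                     rad_locus_id = rad_all[invariant],
                     stringsAsFactors = FALSE)
  keep <- !invariant
  tab <- geno_table(
    variants = data.frame(chrom = chrom[keep], pos = pos[keep],
                          ref = ref[keep], alt = alt[keep],
                          rad_locus_id = rad_all[keep],
                          stringsAsFactors = FALSE),
    geno = dos[keep, , drop = FALSE],
    depth = matrix(as.integer(dp), nrow(dp))[keep, , drop = FALSE],
    samples = samples,
    monomorphic = mono,
    ad_ref = if (!is.null(ad_ref)) ad_ref[keep, , drop = FALSE],
    ad_alt = if (!is.null(ad_alt)) ad_alt[keep, , drop = FALSE])

  if (is.null(popmap_path)) return(tab)
  popmap <- read_popmap(popmap_path)
  unknown <- setdiff(popmap$sample, tab$samples)
  if (length(unknown) > 0)
    stop("popmap names sample(s) absent from the VCF: ",
         paste(unknown, collapse = ", "))
  list(table = tab, popmap = popmap)
}

# GT strings -> alt-allele dosage. Multiallelic genotypes count any non-ref
# allele (such records are only passed through until the biallelic filter).
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    if (!all(grepl("^[0-9]+$", alleles)))
      stop("malformed GT field: '", g, "'")
    sum(alleles != "0")
  }, integer(1))
  m <- matrix(lut[match(as.vector(gt), u)], nrow(gt), ncol(gt))
  colnames(m) <- colnames(gt)
  m
}

#' Write a genotype table as VCF
#'
#' Emits a minimal VCF v4.2 with `GT:DP` (and `AD` when allelic depths are
#' present); monomorphic registry sites are written as invariant records
#' (ALT `.`). RAD-locus membership is recorded in an `RAD=` INFO tag so a
#' read/write round trip preserves the table.
#'
#' @param table a `geno_table`
#' @param path output path
#' @export
write_vcf <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=radpopgen",
    "##INFO=<ID=RAD,Number=1,Type=String,Description=\"RAD locus id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", table$samples), collapse = "\t")), con)
  has_ad <- !is.null(table$ad_ref)
  fmt <- if (has_ad) "GT:DP:AD" else "GT:DP"
  v <- table$variants
  if (nrow(v) > 0) {
    gts <- matrix("./.", nrow(v), length(table$samples))
    gts[table$geno == 0] <- "0/0"
    gts[table$geno == 1] <- "0/1"
    gts[table$geno == 2] <- "1/1"
    cells <- matrix(paste0(gts, ":", table$depth), nrow(v))
    if (has_ad) {
      adr <- table$ad_ref; ada <- table$ad_alt
      adr[is.na(adr)] <- 0; ada[is.na(ada)] <- 0
      cells <- matrix(paste0(cells, ":", adr, ",", ada), nrow(v))
    }
    lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                   paste0("RAD=", v$rad_locus_id), fmt,
                   apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  } else lines <- character()
  m <- table$monomorphic
  if (nrow(m) > 0) {
    radtag <- if (!is.null(m$rad_locus_id)) paste0("RAD=", m$rad_locus_id)
              else "."
    blank <- paste(rep(if (has_ad) "./.:0:0,0" else "./.:0",
                       length(table$samples)), collapse = "\t")
    mlines <- paste(m$chrom, m$pos, ".", "N", ".", ".", "PASS", radtag,
                    fmt, blank, sep = "\t")
    lines <- c(lines, mlines)
  }
  # interleave in (chrom, pos) order
  allchrom <- c(v$chrom, m$chrom)
  allpos <- c(v$pos, m$pos)
  writeLines(lines[order(allchrom, allpos)], con)
  invisible(path)
}

#' Write the monomorphic-site registry as a tab-separated table
#' @param table a `geno_table`
#' @param path output path
#' @export
write_site_registry <- function(table, path) {
  write.table(table$monomorphic, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
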