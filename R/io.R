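#' Read phased genotypes from a VCF file
#'
#' Accepts biallelic sites with fully phased GT fields (`0|1` style).
#' Unphased (`/`), missing (`.`) or multiallelic records are rejected
#' with an error naming the offending record: no silent coercion.
#'
#' @param path VCF file (plain or bgzipped; parsed with \pkg{vcfR}).
#' @param majorIs which allele is coded 1 (the major allele of the model):
#'   `"alt"` (default), `"ref"`, or `"frequency"` (the more frequent
#'   allele per site, ties coded as ALT).
#' @return A [PhasedGenotypes-class] with loci in file order.
#' @export
readPhasedVcf <- function(path, majorIs = c("alt", "ref", "frequency")) {
  majorIs <- match.arg(majorIs)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- which(grepl(",", alt))
  if (length(multi))
    formatError("multiallelic site at %s:%s", fix[multi[1L], "CHROM"],
                fix[multi[1L], "POS"])
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  badMask <- !grepl("^[01]\\|[01]$", gt)
  dim(badMask) <- dim(gt)
  bad <- which(badMask, arr.ind = TRUE)
  if (nrow(bad)) {
    l <- bad[1L, 1L]
    formatError(
      "unphased, missing or invalid GT '%s' at %s:%s (sample %s)",
      gt[bad[1L, 1L], bad[1L, 2L]], fix[l, "CHROM"], fix[l, "POS"],
      colnames(gt)[bad[1L, 2L]])
  }
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  flip <- switch(majorIs,
    alt = rep(FALSE, nrow(a1)),
    ref = rep(TRUE, nrow(a1)),
    frequency = (rowSums(a1) + rowSums(a2)) < ncol(a1))
  a1[flip, ] <- 1L - a1[flip, , drop = FALSE]
  a2[flip, ] <- 1L - a2[flip, , drop = FALSE]
  PhasedGenotypes(a1, a2, ids = colnames(gt), generation = 0L)
}

#' Read and write the haplotype-table TSV dialect
#'
#' Tab-separated, UTF-8, unquoted; header `id  hap  a1 ... aL`; exactly
#' two rows per individual (hap 1 then 2 in any order), alleles 0/1.
#' `writeHaplotypeTsv()` followed by `readHaplotypeTsv()` is the
#' identity.
#'
#' @param path file path.
#' @param x a [PhasedGenotypes-class] to write.
#' @return `readHaplotypeTsv()`: a [PhasedGenotypes-class];
#'   `writeHaplotypeTsv()`: the path, invisibly.
#' @export
readHaplotypeTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 3L || names(tab)[1L] != "id" || names(tab)[2L] != "hap")
    formatError("haplotype TSV must start with columns 'id' and 'hap'")
  key <- paste(tab$id, tab$hap)
  dup <- which(duplicated(key))
  if (length(dup))
    formatError("duplicated (id, hap) row: %s", key[dup[1L]])
  ids <- unique(tab$id)
  for (id in ids) {
    haps <- sort(tab$hap[tab$id == id])
    if (!identical(haps, c("1", "2")))
      formatError("individual '%s' must have exactly haplotype rows 1 and 2",
                  id)
  }
  am <- as.matrix(tab[, -(1:2), drop = FALSE])
  if (!all(am %in% c("0", "1")))
    formatError("non-binary allele in row %d",
                which(!apply(am, 1L, function(z) all(z %in% c("0", "1"))))[1L])
  storage.mode(am) <- "integer"
  h1 <- t(am[tab$hap == "1", , drop = FALSE])
  h2 <- t(am[tab$hap == "2", , drop = FALSE])
  dimnames(h1) <- list(NULL, tab$id[tab$hap == "1"])
  dimnames(h2) <- list(NULL, tab$id[tab$hap == "2"])
  h2 <- h2[, colnames(h1), drop = FALSE]
  PhasedGenotypes(h1, h2, ids = colnames(h1), generation = 0L)
}

#' @rdname readHaplotypeTsv
#' @export
writeHaplotypeTsv <- function(x, path) {
  stopifnot(is(x, "PhasedGenotypes"))
  L <- nLoci(x); N <- nInd(x)
  ids <- indIds(x)
  rows <- matrix("", 2L * N, L + 2L)
  rows[seq(1L, 2L * N, 2L), 1L] <- ids
  rows[seq(2L, 2L * N, 2L), 1L] <- ids
  rows[seq(1L, 2L * N, 2L), 2L] <- "1"
  rows[seq(2L, 2L * N, 2L), 2L] <- "2"
  rows[seq(1L, 2L * N, 2L), -(1:2)] <- t(x@hap1)
  rows[seq(2L, 2L * N, 2L), -(1:2)] <- t(x@hap2)
  header <- c("id", "hap", paste0("a", seq_len(L)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(rows, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read and write the marker-effects TSV dialect
#'
#' Columns `marker` and `beta`, tab-separated, one row per locus in the
#' genotype file's marker order.
#'
#' @param path file path.
#' @param mu overall mean to attach (default 0; the file carries only
#'   per-marker effects).
#' @param trait a [TraitModel-class] to write.
#' @param markers optional marker names for writing (default m1..mL).
#' @return `readEffectsTsv()`: a [TraitModel-class] with the marker names
#'   attached as `names(markerEffects(x))`.
#' @export
readEffectsTsv <- function(path, mu = 0) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE,
                           colClasses = c("character", "numeric"))
  if (!identical(names(tab)[1:2], c("marker", "beta")))
    formatError("effects TSV must have columns 'marker' and 'beta'")
  if (any(!is.finite(tab$beta)))
    formatError("non-finite effect for marker '%s'",
                tab$marker[which(!is.finite(tab$beta))[1L]])
  tr <- TraitModel(tab$beta, mu = mu)
  tr@beta <- stats::setNames(tr@beta, tab$marker)
  tr
}

#' @rdname readEffectsTsv
#' @export
writeEffectsTsv <- function(trait, path, markers = NULL) {
  beta <- trait@beta
  if (is.null(markers))
    markers <- names(beta) %||% paste0("m", seq_along(beta))
  utils::write.table(
    data.frame(marker = markers, beta = as.numeric(beta)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert genetic distance to recombination fraction (Haldane)
#'
#' \eqn{r = 0.5\,(1 - e^{-2d/100})} for a distance d in centimorgans,
#' the no-interference map function matching the Markov meiosis model.
#'
#' @param d distance in cM (>= 0).
#' @return Recombination fraction in \[0, 0.5).
#' @export
haldane <- function(d) 0.5 * (1 - exp(-2 * d / 100))

#' Read and write the genetic-map TSV dialect
#'
#' Columns `marker`, `chrom` and either `pos_cM` (cumulative position in
#' centimorgans; interval lengths are converted with [haldane()]) or
#' `r_next` (the recombination frequency to the next marker; the value on
#' a chromosome's last row is ignored). Rows must follow the genotype
#' file's marker order; chromosome boundaries are forced to r = 0.5.
#'
#' @param path file path.
#' @param map a [GeneticMap-class] to write (emitted in `r_next` form).
#' @param markers optional marker names for writing.
#' @return `readMapTsv()`: a [GeneticMap-class].
#' @export
readMapTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!all(c("marker", "chrom") %in% names(tab)))
    formatError("map TSV must have columns 'marker' and 'chrom'")
  chrom <- as.integer(factor(tab$chrom, levels = unique(tab$chrom)))
  L <- nrow(tab)
  if ("pos_cM" %in% names(tab)) {
    pos <- as.numeric(tab$pos_cM)
    if (any(!is.finite(pos)) || any(pos < 0))
      formatError("negative or missing pos_cM at marker '%s'",
                  tab$marker[which(!is.finite(pos) | pos < 0)[1L]])
    d <- diff(pos)
    samechrom <- diff(chrom) == 0L
    if (any(d[samechrom] < 0))
      formatError("pos_cM decreases within a chromosome at marker '%s'",
                  tab$marker[which(samechrom & d < 0)[1L] + 1L])
    r <- haldane(pmax(d, 0))
  } else if ("r_next" %in% names(tab)) {
    rn <- as.numeric(tab$r_next)
    r <- rn[-L]
    lastOfChrom <- diff(chrom) != 0L
    bad <- which(!lastOfChrom & (!is.finite(r) | r < 0 | r > 0.5))
    if (length(bad))
      formatError("invalid r_next at marker '%s'", tab$marker[bad[1L]])
  } else {
    formatError("map TSV needs a 'pos_cM' or 'r_next' column")
  }
  if (L > 1L) r[diff(chrom) != 0L] <- 0.5
  m <- GeneticMap(if (L > 1L) r else numeric(0), chrom)
  attr(m, "markers") <- as.character(tab$marker)
  m
}

#' @rdname readMapTsv
#' @export
writeMapTsv <- function(map, path, markers = NULL) {
  L <- nLoci(map)
  if (is.null(markers)) markers <- paste0("m", seq_len(L))
  utils::write.table(
    data.frame(marker = markers, chrom = map@chrom,
               r_next = c(map@recomb, NA)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a crosses TSV
#'
#' Two tab-separated columns `parent1` and `parent2`, one row per cross;
#' parents are written as ids when `ids` is supplied, else as indices.
#'
#' @param plan a [MatingPlan-class].
#' @param path file path.
#' @param ids optional individual ids.
#' @export
writeCrossesTsv <- function(plan, path, ids = NULL) {
  p <- plan@pairs
  out <- if (is.null(ids)) data.frame(parent1 = p[, 1L], parent2 = p[, 2L])
  else data.frame(parent1 = ids[p[, 1L]], parent2 = ids[p[, 2L]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a program configuration from YAML
#'
#' Keys mirror the [programConfig()] arguments (`N, S, T, method, W,
#' lambda, gamma, K, nReplicates, seed, evalLambda, nBlocks,
#' maxPasses`); absent keys take the defaults.
#'
#' @param path YAML file.
#' @return A validated `ProgramConfig` list.
#' @export
readProgramConfig <- function(path) {
  y <- yaml::read_yaml(path)
  # unquoted N/T are YAML 1.1 booleans; recover the intended key names
  names(y)[names(y) == "FALSE"] <- "N"
  names(y)[names(y) == "TRUE"] <- "T"
  known <- names(formals(programConfig))
  extra <- setdiff(names(y), known)
  if (length(extra))
    formatError("unknown config key '%s'", extra[1L])
  do.call(programConfig, y)
}
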