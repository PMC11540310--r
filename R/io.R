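#' Write phased genotypes
#'
#' Two plain-text formats: a TSV dialect (rows = markers: chrom, pos_bp, then
#' two haplotype columns per individual) and a minimal phased VCF (GT field
#' only, "|" separator).
#'
#' @param pop a `phased_pop`.
#' @param chrom,pos_bp marker metadata.
#' @param path output file.
#' @param format "tsv" or "vcf".
#' @return `path`, invisibly.
#' @export
write_phased_genotypes <- function(pop, chrom, pos_bp, path,
                                   format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    cols <- list(chrom = chrom, pos_bp = pos_bp)
    for (k in seq_len(n_ind(pop))) {
      cols[[paste0(pop$ids[k], "_h0")]] <- pop$hap0[k, ]
      cols[[paste0(pop$ids[k], "_h1")]] <- pop$hap1[k, ]
    }
    utils::write.table(as.data.frame(cols), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", pop$ids),
                       collapse = "\t")), con)
    gt <- matrix(paste0(t(pop$hap0), "|", t(pop$hap1)),
                 nrow = n_markers(pop))
    body <- cbind(chrom, pos_bp, paste0("m", seq_along(chrom)), "A", "T",
                  ".", "PASS", ".", "GT", gt)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read phased genotypes
#'
#' Reads the TSV dialect or a phased VCF (GT with "|"); unphased separators
#' are rejected with the offending record named.
#'
#' @param path input file.
#' @param format "tsv" or "vcf".
#' @return list: `pop` (`phased_pop`), `chrom`, `pos_bp`.
#' @export
read_phased_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
    hcols <- setdiff(names(d), c("chrom", "pos_bp"))
    h0c <- grep("_h0$", hcols, value = TRUE)
    ids <- sub("_h0$", "", h0c)
    hap0 <- unname(t(as.matrix(d[, paste0(ids, "_h0"), drop = FALSE])))
    hap1 <- unname(t(as.matrix(d[, paste0(ids, "_h1"), drop = FALSE])))
    return(list(pop = phased_pop(hap0, hap1, ids = ids,
                                 generation = "imported"),
                chrom = d$chrom, pos_bp = d$pos_bp))
  }
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  ids <- hdr[-(1:9)]
  rec <- strsplit(body[-1], "\t")
  n_mark <- length(rec)
  chrom <- integer(n_mark); pos <- numeric(n_mark)
  hap0 <- matrix(0L, length(ids), n_mark)
  hap1 <- matrix(0L, length(ids), n_mark)
  for (m in seq_len(n_mark)) {
    f <- rec[[m]]
    chrom[m] <- as.integer(f[1]); pos[m] <- as.numeric(f[2])
    gts <- f[-(1:9)]
    bad <- grep("/", gts, fixed = TRUE)
    if (length(bad))
      stop(sprintf("unphased genotype at %s:%s (sample %s)",
                   f[1], f[2], ids[bad[1]]))
    parts <- strsplit(gts, "|", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop(sprintf("non-diploid genotype at %s:%s", f[1], f[2]))
    al <- matrix(as.integer(unlist(parts)), nrow = 2)
    hap0[, m] <- al[1, ]; hap1[, m] <- al[2, ]
  }
  list(pop = phased_pop(hap0, hap1, ids = ids, generation = "imported"),
       chrom = chrom, pos_bp = pos)
}

config_keys <- function() {
  setdiff(names(formals(program_config)), c())
}

#' Load a program configuration from a key = value text file
#'
#' Lines are `key = value`; `#` starts a comment; unknown keys error. An
#' empty file yields the full defaults.
#'
#' @param path config file.
#' @return a [program_config()].
#' @export
load_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% config_keys())
      stop(sprintf("unknown config key: '%s'", key))
    args[[key]] <- if (key == "strategy") val else as.numeric(val)
  }
  do.call(program_config, args)
}

#' Write simulation results as tidy TSVs plus a manifest
#'
#' Emits `cycles.tsv`, `inbred.tsv`, `plans.tsv` (one row per selected cross
#' per cycle) and `manifest.json` (config snapshot and package version) with
#' stable column order; rewriting is idempotent.
#'
#' @param log a `simulation_log`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(log, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(log$cycles, file.path(dir, "cycles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(log$inbred, file.path(dir, "inbred.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  plan_rows <- do.call(rbind, lapply(seq_along(log$plans), function(t) {
    p <- log$plans[[t]]
    if (is.null(p)) return(NULL)
    cbind(t = t, as.data.frame(p))
  }))
  utils::write.table(plan_rows, file.path(dir, "plans.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(config = unclass(log$config),
                   baseline = log$baseline, sigma_g2 = log$sigma_g2,
                   he0 = log$he0,
                   package_version =
                     as.character(utils::packageVersion("cpsim")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back results written by [write_results()]
#' @param dir directory written by [write_results()].
#' @return list with `cycles`, `inbred`, `plans`, `manifest`.
#' @export
read_results <- function(dir) {
  list(cycles = utils::read.table(file.path(dir, "cycles.tsv"), header = TRUE,
                                  sep = "\t"),
       inbred = utils::read.table(file.path(dir, "inbred.tsv"), header = TRUE,
                                  sep = "\t"),
       plans = utils::read.table(file.path(dir, "plans.tsv"), header = TRUE,
                                 sep = "\t"),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")))
}
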