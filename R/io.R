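#' Read a centroided spectrum from MGF or two-column TSV
#'
#' MGF: the first `BEGIN IONS`/`END IONS` block (use [read_mgf()] for
#' multi-spectrum files); TSV: two columns m/z and intensity, `#` comment
#' lines allowed.
#'
#' @param path file path; format inferred from the extension unless given.
#' @param format `"auto"`, `"mgf"` or `"tsv"`.
#' @return a [spectrum()].
#' @export
read_spectrum <- function(path, format = c("auto", "mgf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "tsv"
  if (format == "mgf") return(read_mgf(path)[[1L]])
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- do.call(rbind, strsplit(trimws(lines), "[\t ]+"))
  spectrum(as.numeric(parts[, 1L]), as.numeric(parts[, 2L]))
}

#' Read / write multi-spectrum MGF files
#'
#' Minimal MGF support: `BEGIN IONS` / `END IONS` blocks with `TITLE`,
#' `PEPMASS` and `CHARGE` headers and "m/z intensity" peak lines.
#'
#' @param path file path.
#' @return `read_mgf`: named list of [spectrum()] objects (names from
#'   `TITLE`), each with attributes `pepmass` and `charge` when present.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) == 0L || length(starts) != length(ends))
    stop("malformed MGF: unmatched BEGIN/END IONS in ", path)
  out <- vector("list", length(starts))
  nms <- character(length(starts))
  for (i in seq_along(starts)) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    hdr <- grepl("=", block, fixed = TRUE)
    fields <- strsplit(block[hdr], "=", fixed = TRUE)
    keys <- toupper(vapply(fields, `[`, character(1), 1L))
    vals <- vapply(fields, function(f) paste(f[-1L], collapse = "="),
                   character(1))
    peaks <- do.call(rbind, strsplit(trimws(block[!hdr]), "[\t ]+"))
    s <- if (is.null(peaks)) spectrum() else
      spectrum(as.numeric(peaks[, 1L]), as.numeric(peaks[, 2L]))
    if ("PEPMASS" %in% keys)
      attr(s, "pepmass") <- as.numeric(strsplit(
        vals[keys == "PEPMASS"][1L], " ")[[1L]][1L])
    if ("CHARGE" %in% keys)
      attr(s, "charge") <- as.integer(sub("\\+$", "",
                                          vals[keys == "CHARGE"][1L]))
    nms[i] <- if ("TITLE" %in% keys) vals[keys == "TITLE"][1L]
              else paste0("spectrum", i)
    out[[i]] <- s
  }
  stats::setNames(out, nms)
}

#' @rdname read_mgf
#' @param spectra named list of [spectrum()] objects.
#' @param pepmass,charge optional per-spectrum vectors for the headers.
#' @export
write_mgf <- function(spectra, path, pepmass = NULL, charge = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", names(spectra)[i]), con)
    pm <- if (!is.null(pepmass)) pepmass[i] else attr(s, "pepmass")
    if (!is.null(pm) && !is.na(pm)) writeLines(paste0("PEPMASS=", pm), con)
    ch <- if (!is.null(charge)) charge[i] else attr(s, "charge")
    if (!is.null(ch) && !is.na(ch)) writeLines(paste0("CHARGE=", ch, "+"),
                                               con)
    writeLines(sprintf("%.6f %.6f", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read peptide specifications from TSV
#'
#' Columns: `id`, `protein`, `positions` (semicolon-separated cysteine
#' positions), `n_cys`, `reduced_mz`, `charge`.
#'
#' @param path file path.
#' @return list of [peptide_spec()] objects, named by id.
#' @export
read_peptide_specs <- function(path) {
  df <- utils::read.delim(path)
  specs <- lapply(seq_len(nrow(df)), function(i) {
    peptide_spec(df$id[i], df$protein[i],
                 as.integer(strsplit(as.character(df$positions[i]),
                                     ";")[[1L]]),
                 df$reduced_mz[i], df$charge[i], df$n_cys[i])
  })
  stats::setNames(specs, df$id)
}

#' Write / read a protein library as FASTA
#'
#' @param proteins named character vector of sequences.
#' @param path file path.
#' @return `write_fasta`: the path, invisibly; `read_fasta`: named
#'   character vector.
#' @export
write_fasta <- function(proteins, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Read a generator configuration file
#'
#' YAML with nested sections per generator (`trajectories`, `library`,
#' `spectra`, `metabolites`); recognized `trajectories` keys are passed
#' straight to [sim_config()].
#'
#' @param path YAML file.
#' @param seed seed overriding any seed in the file (e.g. from the CLI).
#' @return list with a `sim_config` under `$trajectories` and the other
#'   sections as plain lists.
#' @export
read_sim_config <- function(path, seed = NULL) {
  cfg <- yaml::read_yaml(path)
  tr <- cfg$trajectories
  if (!is.null(seed)) tr$seed <- seed
  if (!is.null(tr$label_proportions))
    tr$label_proportions <- unlist(tr$label_proportions)
  cfg$trajectories <- do.call(sim_config, tr)
  if (!is.null(seed)) {
    for (sec in c("library", "spectra", "metabolites"))
      if (!is.null(cfg[[sec]])) cfg[[sec]]$seed <- as.integer(seed)
  }
  cfg
}
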