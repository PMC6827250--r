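# Shared file-format glue. Every file the package writes embeds the package
# version and, where a run is stochastic or configured, the seed and a hash
# of the configuration, so outputs are traceable and byte-reproducible.

pkg_version <- function() {
  as.character(utils::packageVersion("alginseq"))
}

# Polynomial rolling hash over the deparsed object; cheap, dependency-free
# provenance fingerprint (not cryptographic).
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

meta_header_lines <- function(seed = NULL, config = NULL) {
  lines <- sprintf("# alginseq %s", pkg_version())
  if (!is.null(seed)) lines <- c(lines, sprintf("# seed: %d", as.integer(seed)))
  if (!is.null(config)) lines <- c(lines, sprintf("# config_hash: %s", config_hash(config)))
  lines
}

write_tsv_with_header <- function(df, path, seed = NULL, config = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header_lines(seed = seed, config = config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "")
  invisible(path)
}

read_tsv_skip_header <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

report_meta <- function(seed = NULL, config = NULL) {
  m <- list(package = "alginseq", version = pkg_version())
  if (!is.null(seed)) m$seed <- as.integer(seed)
  if (!is.null(config)) m$config_hash <- config_hash(config)
  m
}
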