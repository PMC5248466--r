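# Shared fixture bundles, generated once per test run.

.fx_cache <- new.env(parent = emptyenv())

# the default study-condition scenario (full annotation composition)
default_fixtures <- function() {
  if (is.null(.fx_cache$default)) {
    .fx_cache$default <- generate_fixtures(
      synth_config(seed = 20240101L),
      file.path(tempdir(), "pitmobilome-fx-default"))
  }
  .fx_cache$default
}

# a reduced scenario for fast structural tests
small_config <- function(seed = 7L, ...) {
  synth_config(
    seed = seed, n_supercontigs = 20L, n_mapped = 10L,
    n_host_genes = 40L, n_host_expressed = 30L,
    n_novel = 15L, n_annotated_new = 3L, n_ambiguous = 2L,
    n_no_match = 4L,
    hotspot_counts = c(3L, 3L, 3L),
    mapped_extra_counts = c(2L, 1L),
    n_other_noninsect = 4L, ...)
}

small_fixtures <- function() {
  if (is.null(.fx_cache$small)) {
    .fx_cache$small <- generate_fixtures(
      small_config(), file.path(tempdir(), "pitmobilome-fx-small"))
  }
  .fx_cache$small
}

dir_md5 <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(as.character(tools::md5sum(files)), basename(files))
}
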