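# Copy the installed fixture CSVs into a temp dir so tests can mutate them.
local_fixture_copy <- function(env = parent.frame()) {
  src <- system.file("extdata", package = "degradesign")
  dir <- withr::local_tempdir(.local_envir = env)
  file.copy(list.files(src, full.names = TRUE), dir)
  dir
}

# Write a small CSV and return its path.
local_csv <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = env)
  writeLines(lines, path, useBytes = TRUE)
  path
}
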