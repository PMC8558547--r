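# User-level registry of known archives and their active mounts: one plain
# tab-separated file in the user config directory, rewritten atomically.
# Lines: "archive<TAB>alias<TAB>path<TAB>added" or
#        "mount<TAB>alias<TAB>mountpoint<TAB>pid".

registry_path <- function() {
  dir <- Sys.getenv("FASTAR_CONFIG_DIR", unset = "")
  if (!nzchar(dir)) dir <- tools::R_user_dir("fastar", "config")
  file.path(dir, "registry.tsv")
}

.empty_registry <- function() {
  list(
    archives = data.frame(alias = character(0), path = character(0),
                          added = character(0), stringsAsFactors = FALSE),
    mounts = data.frame(alias = character(0), mountpoint = character(0),
                        pid = integer(0), stringsAsFactors = FALSE)
  )
}

pid_alive <- function(pid) {
  if (!dir.exists("/proc")) return(TRUE)   # no portable probe: keep the entry
  dir.exists(file.path("/proc", pid))
}

#' Load the archive registry
#'
#' Reads the plain-text registry (created on first use). Malformed lines
#' are skipped with a warning, never fatal; mount records whose process is
#' no longer alive are pruned.
#'
#' @param path Registry file (default: the user config directory, or
#'   `$FASTAR_CONFIG_DIR` when set).
#' @return A list with data frames `archives` (alias, path, added) and
#'   `mounts` (alias, mountpoint, pid).
#' @export
registry_load <- function(path = registry_path()) {
  reg <- .empty_registry()
  if (!file.exists(path)) return(reg)
  lines <- readLines(path, warn = FALSE)
  for (ln in lines) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) == 4L && f[1] == "archive") {
      reg$archives <- rbind(reg$archives,
                            data.frame(alias = f[2], path = f[3], added = f[4],
                                       stringsAsFactors = FALSE))
    } else if (length(f) == 4L && f[1] == "mount" &&
               !is.na(suppressWarnings(as.integer(f[4])))) {
      pid <- as.integer(f[4])
      if (pid_alive(pid)) {
        reg$mounts <- rbind(reg$mounts,
                            data.frame(alias = f[2], mountpoint = f[3], pid = pid,
                                       stringsAsFactors = FALSE))
      }
    } else {
      warning("skipping malformed registry line: ", ln, call. = FALSE)
    }
  }
  reg
}

#' @rdname registry_load
#' @param reg A registry list as returned by `registry_load()`.
#' @export
registry_save <- function(reg, path = registry_path()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- c(
    if (nrow(reg$archives))
      paste("archive", reg$archives$alias, reg$archives$path, reg$archives$added,
            sep = "\t"),
    if (nrow(reg$mounts))
      paste("mount", reg$mounts$alias, reg$mounts$mountpoint, reg$mounts$pid,
            sep = "\t")
  )
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(if (is.null(lines)) character(0) else lines, tmp)
  file.rename(tmp, path)   # atomic replace
  invisible(path)
}

registry_add_archive <- function(alias, archive_path, path = registry_path()) {
  if (!file.exists(archive_path)) stop("archive does not exist: ", archive_path)
  reg <- registry_load(path)
  reg$archives <- reg$archives[reg$archives$alias != alias, , drop = FALSE]
  reg$archives <- rbind(reg$archives, data.frame(
    alias = alias, path = normalizePath(archive_path),
    added = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stringsAsFactors = FALSE))
  registry_save(reg, path)
  invisible(reg)
}

registry_resolve <- function(what, path = registry_path()) {
  if (file.exists(what)) return(what)
  reg <- registry_load(path)
  hit <- reg$archives$path[reg$archives$alias == what]
  if (length(hit) == 1L && file.exists(hit)) return(hit)
  fastar_error(sprintf("'%s' is neither an archive file nor a registered alias", what),
               "fastar_lookup")
}
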