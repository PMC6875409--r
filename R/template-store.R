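# Local template store: registered templates and install modules, saved
# filled templates (parameters for reproducibility), search/filter.
#
# Layout under a single root directory:
#   manifest.json   -- entry list {id, name, description, kind, path}
#   templates/      -- registered template XML documents
#   filled/         -- saved filled templates (JSON)

#' Open (and initialise) a template store
#'
#' @param root directory; created if missing.
#' @return A `forge_store` handle.
#' @export
store_open <- function(root) {
  dir.create(file.path(root, "templates"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(root, "filled"), recursive = TRUE,
             showWarnings = FALSE)
  manifest_path <- file.path(root, "manifest.json")
  if (!file.exists(manifest_path))
    writeLines(jsonlite::toJSON(list(entries = list()), auto_unbox = TRUE),
               manifest_path)
  structure(list(root = root), class = "forge_store")
}

#' @export
print.forge_store <- function(x, ...) {
  entries <- store_list(x)
  cat(sprintf("<template store> %s: %d entr%s\n", x$root, nrow(entries),
              if (nrow(entries) == 1) "y" else "ies"))
  invisible(x)
}

read_manifest <- function(store) {
  m <- jsonlite::read_json(file.path(store$root, "manifest.json"))
  m$entries %||% list()
}

write_manifest <- function(store, entries) {
  writeLines(jsonlite::toJSON(list(entries = entries), auto_unbox = TRUE,
                              pretty = TRUE),
             file.path(store$root, "manifest.json"))
  invisible(store)
}

#' Register a template (or install module) in the store
#'
#' Serializes the template under `templates/` and records a manifest entry.
#' Idempotent per id: re-registering the same id updates the entry in
#' place.
#'
#' @param store a `forge_store`.
#' @param t a `forge_template`.
#' @param kind `"template"` or `"install-module"`.
#' @return the manifest entry, invisibly.
#' @export
store_register <- function(store, t, kind = "template") {
  stopifnot(inherits(store, "forge_store"), inherits(t, "forge_template"))
  diags <- validate_template(t)
  errs <- Filter(function(d) d$severity == "error", diags)
  if (length(errs))
    stop("refusing to register invalid template: ",
         format(errs[[1]]), call. = FALSE)
  rel <- file.path("templates", paste0(t$id, ".xml"))
  writeLines(serialize_template(t), file.path(store$root, rel))
  entry <- list(id = t$id, name = t$title, description = t$description,
                kind = kind, path = rel)
  entries <- read_manifest(store)
  idx <- which(vapply(entries, function(e) identical(e$id, t$id),
                      logical(1)))
  if (length(idx)) entries[[idx[1]]] <- entry
  else entries[[length(entries) + 1L]] <- entry
  write_manifest(store, entries)
  invisible(entry)
}

#' List store entries
#' @param store a `forge_store`.
#' @return data.frame with columns id, name, description, kind, path (in
#'   manifest order).
#' @export
store_list <- function(store) {
  entries <- read_manifest(store)
  if (length(entries) == 0)
    return(data.frame(id = character(0), name = character(0),
                      description = character(0), kind = character(0),
                      path = character(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(entries, function(e)
    data.frame(id = e$id, name = e$name %||% "",
               description = e$description %||% "", kind = e$kind,
               path = e$path, stringsAsFactors = FALSE)))
}

#' Search the store
#'
#' Case-insensitive substring match over entry name and description;
#' results keep stable manifest order.
#'
#' @param store a `forge_store`.
#' @param query query text; the empty string matches everything.
#' @return data.frame as [store_list()].
#' @export
store_search <- function(store, query = "") {
  entries <- store_list(store)
  if (!nzchar(query)) return(entries)
  hay <- tolower(paste(entries$name, entries$description))
  entries[grepl(tolower(query), hay, fixed = TRUE), , drop = FALSE]
}

#' Remove an entry from the store
#' @param store a `forge_store`.
#' @param id entry id.
#' @return invisibly, the store.
#' @export
store_remove <- function(store, id) {
  entries <- read_manifest(store)
  idx <- which(vapply(entries, function(e) identical(e$id, id), logical(1)))
  if (length(idx) == 0)
    stop(sprintf("no store entry with id '%s'", id), call. = FALSE)
  path <- file.path(store$root, entries[[idx[1]]]$path)
  if (file.exists(path)) unlink(path)
  write_manifest(store, entries[-idx])
  invisible(store)
}

#' Load a registered template
#' @param store a `forge_store`.
#' @param id entry id.
#' @return a `forge_template`.
#' @export
store_load <- function(store, id) {
  entries <- read_manifest(store)
  idx <- which(vapply(entries, function(e) identical(e$id, id), logical(1)))
  if (length(idx) == 0)
    stop(sprintf("no store entry with id '%s'", id), call. = FALSE)
  parse_template(file.path(store$root, entries[[idx[1]]]$path))
}

# ---- filled templates ------------------------------------------------------

#' Save a filled template
#'
#' Persists the (template, bindings) pair as a JSON document under
#' `filled/` so a run can be reproduced exactly later: reloading and
#' reassembling yields an invocation identical to the one at save time
#' (given the same injected environment). Secret-flagged values are never
#' written.
#'
#' @param store a `forge_store`; the template must be registered.
#' @param t a `forge_template`.
#' @param bindings a `forge_bindings`.
#' @param label human-readable label; also the file name stem.
#' @return the saved file path, invisibly.
#' @export
save_filled <- function(store, t, bindings, label) {
  entries <- read_manifest(store)
  if (!any(vapply(entries, function(e) identical(e$id, t$id), logical(1))))
    stop(sprintf("template '%s' is not registered in the store", t$id),
         call. = FALSE)
  keep <- setdiff(names(bindings$values), bindings$secret)
  doc <- list(
    template_id = t$id,
    content_hash = template_hash(t),
    label = label,
    saved_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    values = bindings$values[keep],
    path_typed = as.list(intersect(bindings$path_typed, keep))
  )
  path <- file.path(store$root, "filled",
                    paste0(make_ident(label), ".json"))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

# order-independent structural hash of the serialized template
template_hash <- function(t) {
  xml <- serialize_template(t)
  # small rolling hash; stability across sessions matters, cryptographic
  # strength does not
  bytes <- utf8ToInt(xml)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%010d", h)
}

#' Load a saved filled template
#'
#' @param store a `forge_store`.
#' @param label the label used at save time.
#' @return list with `template` (reloaded from the store), `bindings`, and
#'   the saved metadata. Errors if the registered template's content hash
#'   no longer matches the saved one.
#' @export
load_filled <- function(store, label) {
  path <- file.path(store$root, "filled",
                    paste0(make_ident(label), ".json"))
  if (!file.exists(path))
    stop(sprintf("no saved run labelled '%s'", label), call. = FALSE)
  doc <- jsonlite::read_json(path)
  t <- store_load(store, doc$template_id)
  if (!identical(template_hash(t), doc$content_hash))
    stop(sprintf(
      "template '%s' changed since the run was saved (hash mismatch)",
      doc$template_id), call. = FALSE)
  bindings <- structure(
    list(values = lapply(doc$values, as.character),
         path_typed = as.character(unlist(doc$path_typed)),
         secret = character(0)),
    class = "forge_bindings")
  list(template = t, bindings = bindings, label = doc$label,
       saved_at = doc$saved_at)
}

#' Reassemble a saved run
#'
#' @param store a `forge_store`.
#' @param label saved-run label.
#' @param env injected environment, as in [assemble_invocation()].
#' @return list of `forge_invocation`.
#' @export
reassemble_filled <- function(store, label, env = NULL) {
  run <- load_filled(store, label)
  assemble_invocation(run$template, run$bindings, env = env)
}
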