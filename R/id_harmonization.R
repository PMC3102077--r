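# Gene-identifier harmonization: canonical spelling, alias/merge resolution and
# gene-model updates (merges, removals, pseudogene demotions) applied to
# identifier sets before any set arithmetic.

ALIAS_STATUSES <- c("current", "merged", "removed", "pseudogene")

# Cosmid-style sequence names: letters, then a digit somewhere in the stem,
# then ".", then digits (e.g. F53B8.1, Y113G7B.21, ZK1151.1).  Matched
# case-insensitively; an optional single trailing lowercase letter is the
# isoform (protein) suffix.
.cosmid_re  <- "^[A-Za-z][A-Za-z0-9]*[0-9][A-Za-z0-9]*\\.[0-9]+"
.isoform_re <- paste0("(", .cosmid_re, ")([a-z])$")

#' Canonicalize a gene identifier
#'
#' Ortholog sources mix protein (isoform) names and gene-level sequence names,
#' and differ in capitalization. The default policy strips a single trailing
#' lowercase isoform letter from cosmid-style sequence names (`F53B8.1a` ->
#' `F53B8.1`) and upper-cases cosmid-style names (`t01c1.3` -> `T01C1.3`);
#' conventional lowercase locus symbols such as `nhr-48` are left untouched.
#' The function is idempotent.
#'
#' @param raw character vector of identifiers.
#' @param strip_isoform strip a single trailing lowercase letter from
#'   cosmid-style names (default `TRUE`).
#' @param fold_case upper-case cosmid-style names (default `TRUE`).
#' @return character vector of canonical identifiers.
#' @examples
#' normalize_id(c("F53B8.1a", "t01c1.3", "nhr-48"))
#' @export
normalize_id <- function(raw, strip_isoform = TRUE, fold_case = TRUE) {
  if (!length(raw)) return(character())
  x <- trimws(raw)
  if (any(!nzchar(x) | is.na(x))) {
    om_stop("orthomeld_invalid_identifier",
            "empty or missing identifier at position %d",
            which(!nzchar(x) | is.na(x))[1])
  }
  if (strip_isoform) {
    x <- sub(.isoform_re, "\\1", x, perl = TRUE)
  }
  if (fold_case) {
    cosmid <- grepl(paste0(.cosmid_re, "$"), x, ignore.case = TRUE)
    x[cosmid] <- toupper(x[cosmid])
    # with isoform stripping off, fold the stem but keep the lowercase suffix
    iso <- grepl(.isoform_re, x) & !cosmid
    x[iso] <- paste0(toupper(substr(x[iso], 1, nchar(x[iso]) - 1L)),
                     substr(x[iso], nchar(x[iso]), nchar(x[iso])))
  }
  x
}

#' Read an alias/status map
#'
#' Tab-separated columns `alias  status  replacement`; `status` is one of
#' `current`, `merged`, `removed`, `pseudogene` and `replacement` is non-empty
#' exactly when `status == "merged"`. `#` comment lines are ignored and the
#' header is optional.
#'
#' @param path file path.
#' @return validated alias map `data.frame` (columns alias, status, replacement).
#' @export
read_alias_map <- function(path) {
  df <- om_read_tsv(path, c("alias", "status", "replacement"))
  validate_alias_map(df)
}

#' Validate an alias map
#'
#' @param alias_map data.frame with columns alias, status, replacement.
#' @return the alias map, invisibly checked, with normalized identifiers.
#' @export
validate_alias_map <- function(alias_map) {
  if (is.null(alias_map) || !nrow(alias_map)) {
    return(data.frame(alias = character(), status = character(),
                      replacement = character(), stringsAsFactors = FALSE))
  }
  stopifnot(all(c("alias", "status", "replacement") %in% names(alias_map)))
  bad <- !alias_map$status %in% ALIAS_STATUSES
  if (any(bad)) {
    om_stop("orthomeld_config_error", "unknown alias status %s for %s",
            sQuote(alias_map$status[bad][1]), alias_map$alias[bad][1])
  }
  alias_map$replacement[is.na(alias_map$replacement)] <- ""
  merged <- alias_map$status == "merged"
  if (any(merged & !nzchar(alias_map$replacement))) {
    om_stop("orthomeld_config_error",
            "merged alias %s lacks a replacement",
            alias_map$alias[merged & !nzchar(alias_map$replacement)][1])
  }
  if (any(!merged & nzchar(alias_map$replacement))) {
    om_stop("orthomeld_config_error",
            "non-merged alias %s must have an empty replacement",
            alias_map$alias[!merged & nzchar(alias_map$replacement)][1])
  }
  if (any(merged & alias_map$replacement == alias_map$alias)) {
    om_stop("orthomeld_config_error", "alias %s merges onto itself",
            alias_map$alias[merged & alias_map$replacement == alias_map$alias][1])
  }
  if (anyDuplicated(alias_map$alias)) {
    om_stop("orthomeld_config_error", "duplicate alias entry for %s",
            alias_map$alias[duplicated(alias_map$alias)][1])
  }
  rownames(alias_map) <- NULL
  alias_map[c("alias", "status", "replacement")]
}

#' Resolve one identifier against an alias map
#'
#' Follows merge chains to a fixed point (an identifier merged into a gene that
#' was itself later merged resolves to the final survivor). Identifiers absent
#' from the map resolve to themselves with status `current`. A chain ending on
#' a removed/pseudogene entry reports that terminal status.
#'
#' @param id a single identifier (canonical).
#' @param alias_map alias map as returned by [read_alias_map()].
#' @param max_depth merge-chain depth limit before a cycle is assumed.
#' @return list with elements `id` (final identifier), `status` (terminal
#'   status: current / merged / removed / pseudogene) and `steps` (number of
#'   merges followed).
#' @examples
#' m <- data.frame(alias = "T01C1.3", status = "merged", replacement = "T01C1.2")
#' resolve_alias("T01C1.3", m)
#' @export
resolve_alias <- function(id, alias_map, max_depth = 100) {
  stopifnot(length(id) == 1)
  alias_map <- validate_alias_map(alias_map)
  .resolve_one(id, .alias_lookup(alias_map), max_depth)
}

.alias_lookup <- function(alias_map) {
  env <- new.env(parent = emptyenv(), size = max(nrow(alias_map), 1L))
  for (i in seq_len(nrow(alias_map))) {
    assign(alias_map$alias[i],
           c(alias_map$status[i], alias_map$replacement[i]), envir = env)
  }
  env
}

.lookup_status <- function(id, lookup) {
  if (exists(id, envir = lookup, inherits = FALSE)) get(id, envir = lookup) else
    c("current", "")
}

.resolve_one <- function(id, lookup, max_depth = 100) {
  cur <- id
  seen <- character()
  steps <- 0L
  repeat {
    rec <- .lookup_status(cur, lookup)
    if (rec[1] != "merged") break
    if (cur %in% seen || steps >= max_depth) {
      om_stop("orthomeld_cyclic_alias",
              "cyclic merge chain: %s", paste(c(seen, cur), collapse = " -> "),
              data = list(cycle = c(seen, cur)))
    }
    seen <- c(seen, cur)
    cur <- rec[2]
    steps <- steps + 1L
  }
  final_status <- .lookup_status(cur, lookup)[1]
  terminal <- if (final_status %in% c("removed", "pseudogene")) final_status
              else if (steps > 0L) "merged" else final_status
  list(id = cur, status = terminal, steps = steps)
}

#' Apply gene-model updates to an identifier set
#'
#' Reproduces the update step applied to published hit lists before comparison:
#' removed and pseudogene entries are dropped (and logged), merged entries are
#' renamed to their surviving gene, and a renamed entry whose target is already
#' present in the set (or arises twice) is dropped as a duplicate merge. Input
#' order is preserved in `kept`.
#'
#' @param ids character vector of identifiers (duplicates permitted).
#' @param alias_map alias map; `NULL` or empty means no updates.
#' @param normalize apply [normalize_id()] first (default `TRUE`).
#' @return an object of class `update_report`: list with `kept` (character),
#'   `renamed` (data.frame old/new), `removed` (data.frame id/reason),
#'   `duplicate_merges` (data.frame old/surviving) and `counts`
#'   (input/kept/removed/duplicate tallies).
#' @examples
#' m <- data.frame(alias = c("F53B8.1", "Y113G7B.21"),
#'                 status = c("merged", "merged"),
#'                 replacement = c("ZK1151.1", "Y113G7B.18"))
#' update_gene_set(c("F53B8.1", "ZK1151.1", "Y113G7B.21"), m)
#' @export
update_gene_set <- function(ids, alias_map = NULL, normalize = TRUE) {
  if (!length(ids)) {
    om_stop("orthomeld_config_error", "empty identifier set")
  }
  if (normalize) ids <- normalize_id(ids)
  alias_map <- validate_alias_map(alias_map)

  lookup <- .alias_lookup(alias_map)
  res <- lapply(ids, .resolve_one, lookup = lookup)
  finals <- vapply(res, `[[`, "", "id")
  status <- vapply(res, `[[`, "", "status")

  # "native" members: inputs that resolve to themselves and survive; a merge
  # target that is itself an input counts as already present in the set.
  native <- new.env(parent = emptyenv())
  for (id in ids[status == "current"]) assign(id, TRUE, envir = native)
  emitted <- new.env(parent = emptyenv())

  kept <- character()
  renamed_old <- renamed_new <- character()
  removed_id <- removed_reason <- character()
  dup_old <- dup_surv <- character()

  for (i in seq_along(ids)) {
    id <- ids[i]; fin <- finals[i]; st <- status[i]
    if (st %in% c("removed", "pseudogene")) {
      removed_id <- c(removed_id, id)
      removed_reason <- c(removed_reason, st)
    } else if (exists(fin, envir = emitted, inherits = FALSE) ||
               (st == "merged" && exists(fin, envir = native, inherits = FALSE))) {
      dup_old <- c(dup_old, id)
      dup_surv <- c(dup_surv, fin)
    } else {
      kept <- c(kept, fin)
      assign(fin, TRUE, envir = emitted)
      if (st == "merged") {
        renamed_old <- c(renamed_old, id)
        renamed_new <- c(renamed_new, fin)
      }
    }
  }

  out <- structure(list(
    kept = kept,
    renamed = data.frame(old = renamed_old, new = renamed_new,
                         stringsAsFactors = FALSE),
    removed = data.frame(id = removed_id, reason = removed_reason,
                         stringsAsFactors = FALSE),
    duplicate_merges = data.frame(old = dup_old, surviving = dup_surv,
                                  stringsAsFactors = FALSE),
    counts = list(input = length(ids), kept = length(kept),
                  removed = length(removed_id), duplicate = length(dup_old))
  ), class = "update_report")
  stopifnot(out$counts$input == out$counts$kept + out$counts$removed +
              out$counts$duplicate,
            !anyDuplicated(out$kept))
  out
}

#' @export
print.update_report <- function(x, ...) {
  cat(sprintf("Gene-model update: %d in -> %d kept (%d removed, %d duplicate merges, %d renamed)\n",
              x$counts$input, x$counts$kept, x$counts$removed,
              x$counts$duplicate, nrow(x$renamed)))
  invisible(x)
}
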