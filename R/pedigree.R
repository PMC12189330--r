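#' Construct a pedigree object from a data frame
#'
#' A `pedigree` is a data frame with one row per animal, ordered so that every
#' parent precedes its offspring, carrying integer parent indices alongside the
#' identifier columns. It is the substrate for all relationship and
#' decomposition computations in this package.
#'
#' @param df data frame with at least columns `id`, `sire`, `dam`. Optional
#'   columns: `sex` ("male"/"female"/"unknown" or "M"/"F"), `birth_date`
#'   (coercible with [as.Date()]), `municipality`, `province`, `alive`
#'   (logical).
#' @param unknown character vector of sentinel tokens treated as an unknown
#'   parent. Herdbook exports vary; the default covers the common ones.
#' @details Parents that are referenced but have no record of their own are
#'   materialized as founder stub rows (flagged in `$stub`): without them the
#'   contribution decompositions would not conserve their totals. Offspring
#'   born before a parent, and records with missing ids, are reported in the
#'   `warnings` attribute; only duplicated ids, self-parentage and parentage
#'   cycles are hard errors.
#' @return An object of class `pedigree`: the validated, topologically ordered
#'   data frame with columns `id`, `sire`, `dam` (NA = unknown), `sex`,
#'   `birth_date`, `municipality`, `province`, `alive`, `stub`, `sire_i`,
#'   `dam_i` (integer row indices, 0 = unknown), and attributes
#'   `founder` (logical) and `warnings` (character).
#' @seealso [read_pedigree()], [validate_and_order()]
#' @export
as_pedigree <- function(df, unknown = c("", "0", "NA", "UNKNOWN")) {
  stopifnot(is.data.frame(df))
  need <- c("id", "sire", "dam")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pedigree is missing mandatory column(s): ", paste(miss, collapse = ", "))

  warnings <- character(0)
  norm <- function(x) {
    x <- trimws(as.character(x))
    x[is.na(x) | x %in% unknown] <- NA_character_
    x
  }
  id <- trimws(as.character(df$id))
  if (anyNA(id) || any(id %in% unknown))
    stop("empty or sentinel-valued animal id in row(s): ",
         paste(which(is.na(id) | id %in% unknown), collapse = ", "))
  if (anyDuplicated(id))
    stop("duplicated animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sire <- norm(df$sire)
  dam  <- norm(df$dam)

  self <- which(!is.na(sire) & sire == id | !is.na(dam) & dam == id)
  if (length(self))
    stop("animal(s) listed as their own parent: ", paste(id[self], collapse = ", "))

  sex <- if ("sex" %in% names(df)) tolower(as.character(df$sex)) else rep(NA_character_, length(id))
  sex[sex %in% c("m", "1")] <- "male"
  sex[sex %in% c("f", "2")] <- "female"
  sex[!sex %in% c("male", "female")] <- "unknown"
  birth_date <- if ("birth_date" %in% names(df)) as.Date(df$birth_date) else as.Date(rep(NA, length(id)))
  municipality <- if ("municipality" %in% names(df)) as.character(df$municipality) else rep(NA_character_, length(id))
  province <- if ("province" %in% names(df)) as.character(df$province) else rep(NA_character_, length(id))
  alive <- if ("alive" %in% names(df)) as.logical(df$alive) else rep(NA, length(id))

  ped <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                    birth_date = birth_date, municipality = municipality,
                    province = province, alive = alive, stub = FALSE,
                    stringsAsFactors = FALSE)

  # materialize referenced-but-undeclared parents as founder stubs
  referenced <- unique(c(sire, dam))
  referenced <- referenced[!is.na(referenced)]
  undeclared <- setdiff(referenced, id)
  if (length(undeclared)) {
    warnings <- c(warnings, paste0("parent(s) without own record added as founder stub(s): ",
                                   paste(undeclared, collapse = ", ")))
    as_sire <- undeclared %in% sire
    stubs <- data.frame(id = undeclared, sire = NA_character_, dam = NA_character_,
                        sex = ifelse(as_sire, "male", "female"),
                        birth_date = as.Date(rep(NA, length(undeclared))),
                        municipality = NA_character_, province = NA_character_,
                        alive = NA, stub = TRUE, stringsAsFactors = FALSE)
    ped <- rbind(stubs, ped)
  }

  ped <- .order_pedigree(ped)

  # date sanity: a child may not be born before a recorded parent
  si <- ped$sire_i; di <- ped$dam_i
  bd <- ped$birth_date
  bad_s <- which(si > 0 & !is.na(bd) & !is.na(bd[pmax(si, 1)]) & bd < bd[pmax(si, 1)])
  bad_d <- which(di > 0 & !is.na(bd) & !is.na(bd[pmax(di, 1)]) & bd < bd[pmax(di, 1)])
  bad <- sort(unique(c(bad_s, bad_d)))
  if (length(bad))
    warnings <- c(warnings, paste0("animal(s) born before a parent: ",
                                   paste(ped$id[bad], collapse = ", ")))

  attr(ped, "warnings") <- warnings
  ped
}

# topological ordering with stable (birth_date, id) tie-break; errors on cycles
.order_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])

  # Kahn's algorithm over parent -> child edges; ready set kept sorted by
  # (birth_date, id) so the order is reproducible
  indeg <- (si > 0L) + (di > 0L)
  children <- vector("list", n)
  for (j in seq_len(n)) {
    if (si[j] > 0L) children[[si[j]]] <- c(children[[si[j]]], j)
    if (di[j] > 0L) children[[di[j]]] <- c(children[[di[j]]], j)
  }
  key_date <- as.numeric(ped$birth_date)
  key_date[is.na(key_date)] <- Inf
  ord <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    ready <- ready[order(key_date[ready], ped$id[ready])]
    v <- ready[1L]; ready <- ready[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) ready <- c(ready, ch)
    }
  }
  if (length(ord) < n) {
    stuck <- setdiff(seq_len(n), ord)
    stop("parentage cycle involving: ", paste(ped$id[stuck], collapse = " -> "))
  }
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  idx <- stats::setNames(seq_len(n), ped$id)
  ped$sire_i <- as.integer(ifelse(is.na(ped$sire), 0L, idx[ped$sire]))
  ped$dam_i  <- as.integer(ifelse(is.na(ped$dam), 0L, idx[ped$dam]))
  attr(ped, "founder") <- ped$sire_i == 0L & ped$dam_i == 0L
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Read a pedigree from CSV
#'
#' @param path path to a CSV file (UTF-8, ISO-8601 dates).
#' @param dialect named character vector mapping the standard column names
#'   (`id`, `sire`, `dam`, `sex`, `birth_date`, `municipality`, `province`,
#'   `alive`) to the file's column names. Unmapped optional columns are
#'   picked up under their standard names when present.
#' @param unknown sentinel tokens denoting an unknown parent.
#' @return A [as_pedigree()] object. Validation warnings (date anomalies,
#'   auto-inserted founder stubs) are collected in the `warnings` attribute.
#' @export
read_pedigree <- function(path, dialect = NULL, unknown = c("", "0", "NA", "UNKNOWN")) {
  if (!file.exists(path)) stop("cannot read pedigree file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      src <- dialect[[std]]
      if (!src %in% names(df)) {
        if (std %in% c("id", "sire", "dam"))
          stop("column '", src, "' (mapped to '", std, "') not found in ", path)
        next
      }
      names(df)[names(df) == src] <- std
    }
  }
  as_pedigree(df, unknown = unknown)
}

#' Write a pedigree to CSV
#'
#' Inverse of [read_pedigree()]: a read-write-read round trip preserves record
#' count, parent links and labels exactly (unknown parents serialized as "0").
#'
#' @param ped pedigree.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "pedigree"))
  out <- ped[, c("id", "sire", "dam", "sex", "birth_date", "municipality",
                 "province", "alive")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  out$birth_date <- ifelse(is.na(out$birth_date), "",
                           format(out$birth_date, "%Y-%m-%d"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate and topologically order a pedigree
#'
#' Re-certifies acyclicity and the parent-before-offspring order. Idempotent:
#' an already ordered pedigree comes back in the same order.
#'
#' @param ped pedigree (or plain data frame acceptable to [as_pedigree()]).
#' @return ordered `pedigree`.
#' @export
validate_and_order <- function(ped) {
  if (!inherits(ped, "pedigree")) return(as_pedigree(ped))
  w <- attr(ped, "warnings")
  out <- .order_pedigree(as.data.frame(ped))
  attr(out, "warnings") <- w
  out
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(attr(x, "founder"))
  cat(sprintf("pedigree: %d animals (%d founders, %d stubs)\n",
              nrow(x), nf, sum(x$stub)))
  w <- attr(x, "warnings")
  if (length(w)) cat("validation notes:\n", paste(" -", w, collapse = "\n"), "\n")
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

#' Equivalent complete generations
#'
#' Pedigree completeness measure: the sum over all known ancestors of
#' (1/2)^depth, computed by the recursion t_i = 1/2 (1 + t_sire) +
#' 1/2 (1 + t_dam) with a missing parent contributing 0. Founders have t = 0.
#'
#' @param ped pedigree.
#' @param ids animal identifiers (default: all).
#' @return named numeric vector of t values.
#' @export
equivalent_complete_generations <- function(ped, ids = ped$id) {
  stopifnot(inherits(ped, "pedigree"))
  pos <- match(ids, ped$id)
  if (anyNA(pos)) stop("unknown id(s): ", paste(ids[is.na(pos)], collapse = ", "))
  n <- nrow(ped)
  t <- numeric(n)
  si <- ped$sire_i; di <- ped$dam_i
  for (i in seq_len(n)) {
    ts <- if (si[i] > 0L) 0.5 * (1 + t[si[i]]) else 0
    td <- if (di[i] > 0L) 0.5 * (1 + t[di[i]]) else 0
    t[i] <- ts + td
  }
  stats::setNames(t[pos], ids)
}

#' Extract a population subset
#'
#' Builds the named study subsets (historical / current / reference) as the
#' conjunction of simple rules: the alive flag, a birth-date window, and the
#' both-parents-known requirement used for gene-origin analyses.
#'
#' @param ped pedigree.
#' @param name label for the subset, e.g. "historical", "current", "reference".
#' @param alive if `TRUE`, keep only animals flagged alive.
#' @param born_after,born_before optional inclusive date bounds.
#' @param both_parents_known if `TRUE`, keep only animals with sire and dam
#'   recorded.
#' @param include_stubs keep auto-inserted founder stubs (default drops them).
#' @return list with `name`, `member_ids`, `n`; empty subsets warn rather than
#'   error.
#' @export
subset_population <- function(ped, name = "subset", alive = FALSE,
                              born_after = NULL, born_before = NULL,
                              both_parents_known = FALSE,
                              include_stubs = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  keep <- rep(TRUE, nrow(ped))
  if (!include_stubs) keep <- keep & !ped$stub
  if (isTRUE(alive)) keep <- keep & !is.na(ped$alive) & ped$alive
  if (!is.null(born_after))
    keep <- keep & !is.na(ped$birth_date) & ped$birth_date >= as.Date(born_after)
  if (!is.null(born_before))
    keep <- keep & !is.na(ped$birth_date) & ped$birth_date <= as.Date(born_before)
  if (isTRUE(both_parents_known)) keep <- keep & ped$sire_i > 0L & ped$dam_i > 0L
  ids <- ped$id[keep]
  if (!length(ids)) warning("subset '", name, "' is empty")
  list(name = name, member_ids = ids, n = length(ids))
}

# internal: positions of ids, with error on misses
.ped_pos <- function(ped, ids) {
  pos <- match(ids, ped$id)
  if (anyNA(pos)) stop("unknown id(s): ", paste(ids[is.na(pos)], collapse = ", "))
  pos
}
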