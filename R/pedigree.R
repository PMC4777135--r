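#' Average numerator relationship matrix (tabular method)
#'
#' Builds the pedigree-based A-matrix by the tabular method: for individual j
#' with parents (s, d), a_jj = 1 + a_sd / 2 and a_jk = (a_ks + a_kd) / 2 for
#' earlier individuals k, with unknown-parent terms contributing 0. Maternal
#' half-sibs with unknown, unrelated sires get the expected 0.25; parent and
#' offspring 0.5.
#'
#' @param ped data.frame with columns `id`, `dam`, `sire`; parents must be
#'   listed as individuals before their offspring; unknown parents are `NA`
#'   or `""`.
#' @return a `rel_kernel` labelled `"A"`.
#' @export
numerator_relationship <- function(ped) {
  ped <- normalize_pedigree(ped)
  ids <- ped$id
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  dam <- ifelse(is.na(ped$dam), 0L, pos[ped$dam])
  sire <- ifelse(is.na(ped$sire), 0L, pos[ped$sire])
  for (j in seq_len(n)) {
    bad <- c(dam[j], sire[j])
    bad <- bad[!is.na(bad) & bad >= j & bad != 0L]
    if (anyNA(c(dam[j], sire[j])) || length(bad))
      stop("pedigree row ", j, " (id '", ids[j],
           "'): parent not listed earlier in the pedigree")
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  entry <- function(a, b) if (a == 0L || b == 0L) 0 else A[a, b]
  for (j in seq_len(n)) {
    if (j > 1L) for (k in seq_len(j - 1L)) {
      A[k, j] <- A[j, k] <- 0.5 * (entry(k, dam[j]) + entry(k, sire[j]))
    }
    A[j, j] <- 1 + 0.5 * entry(dam[j], sire[j])
  }
  rel_kernel(A, "A")
}

normalize_pedigree <- function(ped) {
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(ped))) stop("pedigree needs columns id, dam, sire")
  ped <- ped[, need]
  for (col in need) {
    v <- as.character(ped[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    ped[[col]] <- v
  }
  if (anyNA(ped$id)) stop("pedigree contains a missing id")
  if (anyDuplicated(ped$id))
    stop("duplicate pedigree id: ", ped$id[duplicated(ped$id)][1])
  known <- c(ped$dam, ped$sire)
  known <- unique(known[!is.na(known)])
  missing_parents <- setdiff(known, ped$id)
  if (length(missing_parents))
    stop("pedigree references unknown individual(s): ",
         paste(utils::head(missing_parents, 5), collapse = ", "))
  ped
}

#' Half-sib pedigree assumed for open-pollinated families
#'
#' The operational pedigree of an OP trial: each family's dam is a founder,
#' every offspring lists that dam and an unknown sire. Under this pedigree
#' the A-matrix gives all within-family pairs the half-sib 0.25.
#'
#' @param offspring_ids character vector of offspring ids.
#' @param family family label per offspring (dam id derived as the label).
#' @param dam_ids optional explicit dam id per offspring (default: family).
#' @return pedigree data.frame (`id`, `dam`, `sire`), founders first.
#' @export
assumed_op_pedigree <- function(offspring_ids, family, dam_ids = NULL) {
  family <- as.character(family)
  if (length(family) != length(offspring_ids))
    stop("family must align with offspring_ids")
  if (is.null(dam_ids)) dam_ids <- family
  founders <- unique(dam_ids)
  rbind(
    data.frame(id = founders, dam = NA_character_, sire = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = as.character(offspring_ids), dam = as.character(dam_ids),
               sire = NA_character_, stringsAsFactors = FALSE)
  )
}
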