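# drop readr's spec/problems attributes so readers return plain tibbles
as_plain_tibble <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Read a genealogy file
#'
#' Reads a genealogy CSV with one row per individual and columns
#' `person_id,father_id,mother_id,sex,birth_year,born_in_state,death_year`.
#' Empty fields mean "unknown": a missing parent terminates traversal, a
#' missing birth year makes the individual uncohortable (see
#' [assign_cohort()]).
#'
#' @param path Path to a CSV file.
#' @return A validated genealogy tibble (see [validate_genealogy()]).
#' @export
read_genealogy <- function(path) {
  ped <- readr::read_csv(
    path,
    col_types = readr::cols(
      person_id = readr::col_character(),
      father_id = readr::col_character(),
      mother_id = readr::col_character(),
      sex = readr::col_character(),
      birth_year = readr::col_integer(),
      born_in_state = readr::col_logical(),
      death_year = readr::col_integer()
    ),
    na = ""
  )
  validate_genealogy(as_plain_tibble(ped))
}

#' Validate a genealogy tibble
#'
#' Checks the structural invariants the relative-enumeration and cohort code
#' rely on: unique person ids, parent ids that resolve to rows of the table,
#' sex in `M`/`F`, an acyclic parent graph (nobody is their own ancestor),
#' and `birth_year <= death_year` where both are present.
#'
#' @param ped A data frame with columns `person_id`, `father_id`,
#'   `mother_id`, `sex`, `birth_year`, `born_in_state`, `death_year`.
#' @return The input as a tibble, invisibly checked.
#' @export
validate_genealogy <- function(ped) {
  ped <- tibble::as_tibble(ped)
  needed <- c("person_id", "father_id", "mother_id", "sex", "birth_year",
              "born_in_state", "death_year")
  missing_cols <- setdiff(needed, names(ped))
  if (length(missing_cols) > 0) {
    stop("genealogy is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(ped$person_id) || anyDuplicated(ped$person_id) > 0) {
    stop("person_id must be present and unique", call. = FALSE)
  }
  parents <- c(ped$father_id, ped$mother_id)
  unknown <- setdiff(stats::na.omit(parents), ped$person_id)
  if (length(unknown) > 0) {
    stop("parent ids not present as individuals: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  bad_sex <- setdiff(stats::na.omit(unique(ped$sex)), c("M", "F"))
  if (length(bad_sex) > 0) {
    stop("sex must be 'M' or 'F'", call. = FALSE)
  }
  bad_years <- !is.na(ped$birth_year) & !is.na(ped$death_year) &
    ped$death_year < ped$birth_year
  if (any(bad_years)) {
    stop("death_year precedes birth_year for: ",
         paste(utils::head(ped$person_id[bad_years], 5), collapse = ", "),
         call. = FALSE)
  }
  # acyclicity: ancestor depth is finite for everyone
  invisible(ancestor_depths(ped))
  ped
}

# father/mother row indexes for O(1) parent lookup; 0 = unknown
parent_index <- function(ped) {
  list(
    father = ifelse(is.na(ped$father_id), 0L,
                    match(ped$father_id, ped$person_id)),
    mother = ifelse(is.na(ped$mother_id), 0L,
                    match(ped$mother_id, ped$person_id))
  )
}

# depth of the deepest recorded ancestor chain per row (self = 1);
# errors on a parent cycle
ancestor_depths <- function(ped) {
  idx <- parent_index(ped)
  n <- nrow(ped)
  depth <- rep(NA_integer_, n)
  state <- integer(n) # 0 unvisited, 1 in progress, 2 done
  for (start in seq_len(n)) {
    if (state[start] == 2L) next
    stack <- start
    while (length(stack) > 0) {
      i <- stack[length(stack)]
      if (state[i] == 2L) {
        stack <- stack[-length(stack)]
        next
      }
      f <- idx$father[i]
      m <- idx$mother[i]
      pending <- c(
        if (f > 0L && state[f] != 2L) f,
        if (m > 0L && state[m] != 2L) m
      )
      if (length(pending) > 0) {
        if (any(state[pending] == 1L)) {
          stop("parent graph contains a cycle involving ",
               ped$person_id[i], call. = FALSE)
        }
        state[i] <- 1L
        stack <- c(stack, pending)
      } else {
        depth[i] <- 1L + max(0L, depth[f][f > 0L], depth[m][m > 0L])
        state[i] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  depth
}

row_of <- function(ped, id) {
  i <- match(id, ped$person_id)
  if (is.na(i)) stop("unknown person_id: ", id, call. = FALSE)
  i
}

# ids of recorded parents of each id in `ids`
parents_of <- function(ped, ids) {
  rows <- match(ids, ped$person_id)
  unique(stats::na.omit(c(ped$father_id[rows], ped$mother_id[rows])))
}

children_of <- function(ped, ids) {
  ped$person_id[(!is.na(ped$father_id) & ped$father_id %in% ids) |
                  (!is.na(ped$mother_id) & ped$mother_id %in% ids)]
}

# full siblings: both parents recorded and identical to those of `id`
full_siblings_of <- function(ped, id) {
  i <- row_of(ped, id)
  f <- ped$father_id[i]
  m <- ped$mother_id[i]
  if (is.na(f) || is.na(m)) return(character(0))
  sib <- !is.na(ped$father_id) & !is.na(ped$mother_id) &
    ped$father_id == f & ped$mother_id == m & ped$person_id != id
  ped$person_id[sib]
}

# half siblings: exactly one shared recorded parent
half_siblings_of <- function(ped, id) {
  i <- row_of(ped, id)
  f <- ped$father_id[i]
  m <- ped$mother_id[i]
  share_f <- if (is.na(f)) rep(FALSE, nrow(ped)) else
    !is.na(ped$father_id) & ped$father_id == f
  share_m <- if (is.na(m)) rep(FALSE, nrow(ped)) else
    !is.na(ped$mother_id) & ped$mother_id == m
  half <- xor(share_f, share_m) & ped$person_id != id
  ped$person_id[half]
}

#' First-degree relatives
#'
#' Returns the genetic first-degree relatives of an individual: recorded
#' parents, full siblings (both parents recorded and shared) and children.
#' Half-siblings are second degree; spouses are not relatives. Degree is the
#' minimal kinship path, so an individual never appears in both the first-
#' and second-degree set.
#'
#' @param ped A genealogy tibble (see [read_genealogy()]).
#' @param id A `person_id` present in `ped`.
#' @return Character vector of person ids (no particular order, no
#'   duplicates, never containing `id`).
#' @seealso [second_degree_relatives()]
#' @export
first_degree_relatives <- function(ped, id) {
  row_of(ped, id)
  out <- c(parents_of(ped, id), full_siblings_of(ped, id),
           children_of(ped, id))
  setdiff(unique(out), id)
}

#' Second-degree relatives
#'
#' Returns genetic second-degree relatives: grandparents, grandchildren,
#' aunts/uncles (full siblings of parents), nieces/nephews (children of full
#' siblings) and half-siblings. When both a first- and a second-degree path
#' exist, the closer degree wins, so the result is disjoint from
#' [first_degree_relatives()].
#'
#' @inheritParams first_degree_relatives
#' @return Character vector of person ids.
#' @export
second_degree_relatives <- function(ped, id) {
  row_of(ped, id)
  pars <- parents_of(ped, id)
  kids <- children_of(ped, id)
  sibs <- full_siblings_of(ped, id)
  out <- c(
    parents_of(ped, pars),                                  # grandparents
    children_of(ped, kids),                                 # grandchildren
    unlist(lapply(pars, full_siblings_of, ped = ped)),      # aunts/uncles
    children_of(ped, sibs),                                 # nieces/nephews
    half_siblings_of(ped, id)
  )
  setdiff(unique(out), c(id, first_degree_relatives(ped, id)))
}

#' Relatives of a set of probands
#'
#' Deduplicated union of per-proband relative sets at a given degree.
#' Probands themselves are never counted as relatives: within one analysis
#' group a person related to several probands is counted once, and genotyped
#' probands are excluded from each other's relative sets.
#'
#' @param ped A genealogy tibble.
#' @param ids Proband person ids.
#' @param degree 1 or 2.
#' @param exclude Additional person ids to drop from the union (defaults to
#'   `ids`).
#' @return Character vector of person ids.
#' @export
relative_set <- function(ped, ids, degree = 1, exclude = ids) {
  stopifnot(degree %in% c(1, 2))
  fun <- if (degree == 1) first_degree_relatives else second_degree_relatives
  out <- unique(unlist(lapply(ids, fun, ped = ped)))
  setdiff(out, exclude)
}

#' Generations of genealogy linked to an individual
#'
#' Depth of the deepest recorded ancestor chain, counting the individual
#' itself: a founder is 1, someone with a recorded parent is 2, someone with
#' a recorded grandparent is at least 3, and so on. Missing parents simply
#' terminate chains. This is the quantity behind the "at least three
#' generations of genealogy" eligibility filter.
#'
#' @param ped A genealogy tibble.
#' @param ids Person ids to evaluate; defaults to everyone.
#' @return A tibble with columns `person_id` and `generations`.
#' @export
generations_linked <- function(ped, ids = ped$person_id) {
  depth <- ancestor_depths(ped)
  rows <- match(ids, ped$person_id)
  if (anyNA(rows)) {
    stop("unknown person_id: ", paste(ids[is.na(rows)], collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(person_id = ids, generations = depth[rows])
}

#' Filter probands by genealogical depth
#'
#' Keeps probands whose linked genealogy spans at least `min_generations`
#' generations (ancestor-chain depth including self), preserving input
#' order. Probands absent from the genealogy are treated as unlinked and
#' dropped, with a message giving the count.
#'
#' @param probands A tibble with a `person_id` column (e.g. from
#'   [read_probands()]).
#' @param ped A genealogy tibble.
#' @param min_generations Minimum depth, default 3.
#' @return The filtered proband tibble.
#' @export
eligible_probands <- function(probands, ped, min_generations = 3) {
  stopifnot(min_generations >= 1)
  linked <- probands$person_id %in% ped$person_id
  if (any(!linked)) {
    message(sum(!linked), " proband(s) not linked to the genealogy; dropped")
  }
  kept <- probands[linked, , drop = FALSE]
  if (nrow(kept) == 0) return(tibble::as_tibble(kept))
  depth <- generations_linked(ped, kept$person_id)$generations
  tibble::as_tibble(kept[depth >= min_generations, , drop = FALSE])
}

#' Read a proband file
#'
#' Proband CSV with header `person_id,g_allele_carrier`; the carrier flag is
#' a resolved per-person genotype call (see [resolve_calls()]), not raw
#' assay data.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `person_id` (character) and
#'   `g_allele_carrier` (logical).
#' @export
read_probands <- function(path) {
  as_plain_tibble(readr::read_csv(
    path,
    col_types = readr::cols(
      person_id = readr::col_character(),
      g_allele_carrier = readr::col_logical()
    ),
    na = ""
  ))
}
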