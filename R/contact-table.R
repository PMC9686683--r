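#' Parse DNA base tokens
#'
#' A base token is a lowercase nucleotide, a strand letter and a fragment
#' position, e.g. `"gA6"` (guanine, strand A, position 6) or `"aB20"`.
#'
#' @param x character vector of base tokens.
#' @return a tibble with columns `base` (uppercase nucleotide), `strand`
#'   (`"A"` or `"B"`) and `position` (integer).
#' @examples
#' parse_base_token(c("gA6", "aB20"))
#' @export
parse_base_token <- function(x) {
  m <- regmatches(x, regexec("^([acgt])([AB])([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    abort(sprintf(
      "malformed DNA base token(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ), class = "dbd_parse_error")
  }
  tibble(
    base = toupper(vapply(m, `[`, character(1), 2L)),
    strand = vapply(m, `[`, character(1), 3L),
    position = as.integer(vapply(m, `[`, character(1), 4L))
  )
}

#' Parse protein residue tokens
#'
#' A residue token is a one-letter amino-acid code, a chain identifier and
#' a residue number, e.g. `"QB197"` (glutamine, chain B, residue 197).
#'
#' @param x character vector of residue tokens.
#' @return a tibble with columns `aa`, `prot_chain` and `prot_number`.
#' @examples
#' parse_residue_token("QB197")
#' @export
parse_residue_token <- function(x) {
  m <- regmatches(x, regexec("^([A-Z])([A-Za-z0-9])([0-9]+)$", x))
  ok <- vapply(m, length, integer(1)) == 4L
  aa <- rep(NA_character_, length(x))
  aa[ok] <- vapply(m[ok], `[`, character(1), 2L)
  bad <- !ok | !(aa %in% AA1)
  if (any(bad)) {
    abort(sprintf(
      "malformed protein residue token(s): %s",
      paste(unique(x[bad]), collapse = ", ")
    ), class = "dbd_parse_error")
  }
  tibble(
    aa = aa,
    prot_chain = vapply(m, `[`, character(1), 3L),
    prot_number = as.integer(vapply(m, `[`, character(1), 4L))
  )
}

#' Format base / residue tokens
#'
#' Inverse of [parse_base_token()] and [parse_residue_token()]; formatting a
#' parsed token round-trips exactly.
#'
#' @param base,strand,position components of a DNA base identifier.
#' @return character vector of tokens.
#' @export
format_base_token <- function(base, strand, position) {
  paste0(tolower(base), strand, position)
}

#' @rdname format_base_token
#' @param aa,prot_chain,prot_number components of a protein residue
#'   identifier.
#' @export
format_residue_token <- function(aa, prot_chain, prot_number) {
  paste0(aa, prot_chain, prot_number)
}

new_contact_map <- function(df) {
  df <- as_tibble(df)
  class(df) <- c("dbd_contact_map", class(df))
  df
}

#' Construct a contact map
#'
#' A contact map is a tidy table of protein-residue / DNA-base contact
#' records for one or more candidate DNA-binding domains, split by contact
#' class (`"protein-backbone"` vs `"protein-side-chain"`).  Duplicate
#' (residue, base, class) triples within a domain are collapsed, keeping the
#' smallest minimum distance.
#'
#' @param records a data frame with columns `domain_id`, `aa`, `prot_chain`,
#'   `prot_number`, `base`, `strand`, `position`, `contact_class` and
#'   optionally `min_distance` and `fragment_length`.
#' @param strict_positions if `TRUE`, require every base position to lie in
#'   `1..2L` for the declared fragment length `L`.  Off by default: printed
#'   contact tables can carry fragment-global numbering outside that range.
#' @return a `dbd_contact_map` tibble.
#' @export
contact_map <- function(records, strict_positions = FALSE) {
  records <- as_tibble(records)
  require_columns(records, c(
    "domain_id", "aa", "prot_chain", "prot_number",
    "base", "strand", "position", "contact_class"
  ), "contact map")
  if (!"min_distance" %in% names(records)) records$min_distance <- NA_real_
  if (!"fragment_length" %in% names(records)) {
    records$fragment_length <- NA_integer_
  }
  if (!all(records$contact_class %in% CONTACT_CLASSES)) {
    abort(sprintf(
      "contact_class must be one of: %s",
      paste(CONTACT_CLASSES, collapse = ", ")
    ))
  }
  if (!all(records$strand %in% c("A", "B"))) {
    abort("strand must be \"A\" or \"B\"")
  }
  if (!all(records$base %in% NUCS)) {
    abort("base must be one of A, C, G, T")
  }
  if (any(records$position < 1L)) {
    abort("base positions must be positive integers")
  }
  if (strict_positions) {
    bad <- !is.na(records$fragment_length) &
      records$position > 2L * records$fragment_length
    if (any(bad)) {
      abort(sprintf(
        "base position(s) outside 1..2L for fragment length: %s",
        paste(unique(records$position[bad]), collapse = ", ")
      ))
    }
  }
  records |>
    group_by(across(c(
      "domain_id", "fragment_length", "aa", "prot_chain", "prot_number",
      "base", "strand", "position", "contact_class"
    ))) |>
    summarise(min_distance = suppressWarnings(min(.data$min_distance)),
              .groups = "drop") |>
    mutate(min_distance = ifelse(is.finite(.data$min_distance),
                                 .data$min_distance, NA_real_)) |>
    arrange(.data$domain_id, .data$contact_class, .data$prot_chain,
            .data$prot_number, .data$position) |>
    new_contact_map()
}

#' Read a contact table
#'
#' Reads the tab-separated contact dialect: a header line followed by one
#' record per row with columns `domain_id`, `residue` (residue token such as
#' `"QB197"`), `base` (base token such as `"gA6"`), `contact_class`, and
#' optionally `min_distance` and `fragment_length`.  Minimum distances are
#' absent when the table was transcribed from a printed contact list rather
#' than computed from structure.
#'
#' @param path path to the TSV file.
#' @param strict_positions passed to [contact_map()].
#' @return a `dbd_contact_map` tibble.
#' @seealso [write_contact_table()] for the companion writer; the pair
#'   round-trips exactly.
#' @export
read_contact_table <- function(path, strict_positions = FALSE) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  require_columns(raw, c("domain_id", "residue", "base", "contact_class"),
                  sprintf("contact table '%s'", path))
  parse_one <- function(i) {
    res <- tryCatch(
      cbind(parse_residue_token(raw$residue[i]), parse_base_token(raw$base[i])),
      error = function(e) {
        abort(sprintf("%s: line %d: %s", path, i + 1L, conditionMessage(e)),
              class = "dbd_parse_error")
      }
    )
    res
  }
  parsed <- purrr::map_dfr(seq_len(nrow(raw)), parse_one)
  records <- tibble(
    domain_id = raw$domain_id,
    fragment_length = if ("fragment_length" %in% names(raw)) {
      as.integer(raw$fragment_length)
    } else NA_integer_,
    parsed,
    contact_class = raw$contact_class,
    min_distance = if ("min_distance" %in% names(raw)) {
      as.numeric(raw$min_distance)
    } else NA_real_
  )
  contact_map(records, strict_positions = strict_positions)
}

#' Write a contact table
#'
#' @param cm a `dbd_contact_map` tibble (see [contact_map()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_table <- function(cm, path) {
  out <- tibble(
    domain_id = cm$domain_id,
    residue = format_residue_token(cm$aa, cm$prot_chain, cm$prot_number),
    base = format_base_token(cm$base, cm$strand, cm$position),
    contact_class = cm$contact_class,
    min_distance = cm$min_distance,
    fragment_length = cm$fragment_length
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
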