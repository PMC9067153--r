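#' Progression-stage gene signatures by set algebra
#'
#' The three signatures intersect the per-comparison integrated gene lists
#' of the four-stage progression model (melan-a -> 4C -> 4C11- -> 4C11+),
#' requiring the *same* expression direction in every supporting
#' comparison:
#'
#' * **malignancy** — altered in 4C, 4C11- and 4C11+ relative to melan-a
#'   (all three parental comparisons).
#' * **EMT** — elevated (or reduced) in the mesenchymal pair relative to
#'   both differentiated lines: up in 4C and 4C11- vs melan-a *and* down in
#'   4C11+ vs 4C and vs 4C11- (down members mirror-imaged).
#' * **metastasis** — altered in the same direction in 4C11+ relative to
#'   all three other lines, and by default absent from the melan-a vs 4C
#'   and melan-a vs 4C11- lists (the "only in 4C11+" clause;
#'   `exclusive = FALSE` lifts it).
#'
#' @param integrated Integrated results for all needed comparisons: one
#'   tibble as returned by [integrate_comparison()] (rows from several
#'   comparisons bound together), or a list of such tibbles.
#' @param lines Named character vector mapping the four roles `parent`,
#'   `premalignant`, `nonmetastatic`, `metastatic` to group labels.
#' @return An `epi_signature`: a tibble `gene_id`, `direction`, `mode`,
#'   `supported_by`, with the signature name in attribute `"name"`.
#' @name signatures
NULL

default_lines <- function() {
  c(parent = "melan-a", premalignant = "4C", nonmetastatic = "4C11-",
    metastatic = "4C11+")
}

as_integrated_tbl <- function(integrated) {
  if (is.data.frame(integrated)) integrated else dplyr::bind_rows(integrated)
}

# distinct (gene, direction, mode) membership of one ordered comparison
comparison_members <- function(integrated, a, b) {
  d <- dplyr::filter(integrated, .data$group_a == a, .data$group_b == b)
  if (nrow(d) == 0)
    abort(paste0("missing comparison: ", comparison_label(a, b)))
  dplyr::distinct(d, .data$gene_id, .data$expr_direction, .data$mode)
}

new_signature <- function(members, name) {
  out <- dplyr::arrange(members, .data$gene_id)
  if (anyDuplicated(out$gene_id))
    abort("internal error: gene in both up and down sets.")
  attr(out, "name") <- name
  class(out) <- c("epi_signature", class(out))
  out
}

#' @export
print.epi_signature <- function(x, ...) {
  cat("<epi_signature>", attr(x, "name", exact = TRUE), "-", sum(x$direction == "up"),
      "up /", sum(x$direction == "down"), "down genes\n")
  NextMethod()
}

as_signature_tbl <- function(signature) {
  if (!is.data.frame(signature) ||
      !all(c("gene_id", "direction") %in% names(signature)))
    abort("signature must have columns gene_id and direction.")
  if (!all(signature$direction %in% c("up", "down")))
    abort("signature direction must be 'up' or 'down'.")
  tibble::as_tibble(signature)
}

# genes present with one consistent direction in every listed comparison,
# with orientation flips: flip = TRUE means the required direction in that
# comparison is the opposite of the signature direction
consistent_members <- function(integrated, comps, flips) {
  tabs <- purrr::map2(comps, flips, function(cp, fl) {
    m <- comparison_members(integrated, cp[1], cp[2])
    dplyr::transmute(
      m, gene_id = .data$gene_id,
      sig_direction = if (fl) flip_direction(.data$expr_direction)
                      else .data$expr_direction
    ) |> dplyr::distinct()
  })
  joint <- purrr::reduce(tabs, dplyr::inner_join,
                         by = c("gene_id", "sig_direction"))
  dplyr::rename(joint, direction = "sig_direction")
}

flip_direction <- function(x) ifelse(x == "up", "down", "up")

# attach the mode recorded in a reference comparison (first hit wins)
attach_mode <- function(members, integrated, ref_comps) {
  modes <- purrr::map(ref_comps, function(cp) {
    dplyr::filter(integrated, .data$group_a == cp[1],
                  .data$group_b == cp[2]) |>
      dplyr::distinct(.data$gene_id, .data$mode)
  }) |>
    dplyr::bind_rows() |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  dplyr::left_join(members, modes, by = "gene_id")
}

#' @rdname signatures
#' @export
signature_malignancy <- function(integrated, lines = default_lines()) {
  integrated <- as_integrated_tbl(integrated)
  comps <- list(c(lines[["parent"]], lines[["premalignant"]]),
                c(lines[["parent"]], lines[["nonmetastatic"]]),
                c(lines[["parent"]], lines[["metastatic"]]))
  members <- consistent_members(integrated, comps, flips = c(FALSE, FALSE,
                                                             FALSE))
  members <- attach_mode(members, integrated, comps[3]) |>
    dplyr::mutate(supported_by = paste(
      purrr::map_chr(comps, ~ comparison_label(.x[1], .x[2])),
      collapse = ";"
    ))
  new_signature(members, "malignancy")
}

#' @rdname signatures
#' @export
signature_emt <- function(integrated, lines = default_lines()) {
  integrated <- as_integrated_tbl(integrated)
  comps <- list(c(lines[["parent"]], lines[["premalignant"]]),
                c(lines[["parent"]], lines[["nonmetastatic"]]),
                c(lines[["premalignant"]], lines[["metastatic"]]),
                c(lines[["nonmetastatic"]], lines[["metastatic"]]))
  # an EMT-up gene is up in the mesenchymal lines vs melan-a and down again
  # in differentiated 4C11+ vs either mesenchymal line
  members <- consistent_members(integrated, comps,
                                flips = c(FALSE, FALSE, TRUE, TRUE))
  members <- attach_mode(members, integrated, comps[1]) |>
    dplyr::mutate(supported_by = paste(
      purrr::map_chr(comps, ~ comparison_label(.x[1], .x[2])),
      collapse = ";"
    ))
  new_signature(members, "EMT")
}

#' @rdname signatures
#' @param exclusive Enforce the "altered only in the metastatic line"
#'   clause by excluding genes present in the parental comparisons against
#'   the premalignant or nonmetastatic lines.
#' @export
signature_metastasis <- function(integrated, lines = default_lines(),
                                 exclusive = TRUE) {
  integrated <- as_integrated_tbl(integrated)
  comps <- list(c(lines[["parent"]], lines[["metastatic"]]),
                c(lines[["premalignant"]], lines[["metastatic"]]),
                c(lines[["nonmetastatic"]], lines[["metastatic"]]))
  members <- consistent_members(integrated, comps,
                                flips = c(FALSE, FALSE, FALSE))
  if (exclusive) {
    other <- dplyr::filter(
      integrated,
      .data$group_a == lines[["parent"]],
      .data$group_b %in% c(lines[["premalignant"]],
                           lines[["nonmetastatic"]])
    )
    members <- dplyr::filter(members, !.data$gene_id %in% other$gene_id)
  }
  members <- attach_mode(members, integrated, comps[1]) |>
    dplyr::mutate(supported_by = paste(
      purrr::map_chr(comps, ~ comparison_label(.x[1], .x[2])),
      collapse = ";"
    ))
  new_signature(members, "metastasis")
}
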