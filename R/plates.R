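# 384-well plate layouts with the screen's control geometry.

# Control triplets sit in the inner region at upper-left, centre and
# bottom-right anchors; DMSO (negative) and 5-FU (positive) rows alternate so
# both roles sample the same plate regions.
.control_wells <- function() {
  list(
    dmso_control = c("C3", "C4", "C5", "H12", "H13", "H14", "N20", "N21", "N22"),
    pos_control  = c("D3", "D4", "D5", "I12", "I13", "I14", "M20", "M21", "M22")
  )
}

#' Lay a compound library out on 384-well plates
#'
#' Only the inner 240 wells of each 16 x 24 plate are used (outermost two
#' rows/columns are buffer). Each plate carries nine DMSO and nine positive
#' (5-FU) control wells in triplets at the upper-left, centre and
#' bottom-right of the inner region; the remaining 222 wells take compounds
#' in column-major order. The last plate may be partially filled.
#'
#' @param library Compound tibble from [build_library()] (needs
#'   `compound_id`).
#' @return A tibble with columns `plate_id`, `well`, `row`, `col`, `role`
#'   (`compound`, `dmso_control`, `pos_control`, `buffer`) and `compound_id`
#'   (`NA` except for compound wells). Buffer wells are included so a layout
#'   row exists for all 384 wells.
#' @export
#' @examples
#' lay <- build_plate_layouts(build_library(seed = 1))
#' dplyr::count(lay, plate_id, role)
build_plate_layouts <- function(library) {
  if (nrow(library) == 0) {
    return(tibble(plate_id = character(), well = character(),
                  row = character(), col = integer(),
                  role = character(), compound_id = character()))
  }
  ctl <- .control_wells()
  inner <- inner_wells()
  cpd_wells <- setdiff(inner, unlist(ctl))
  per_plate <- length(cpd_wells)                     # 240 - 18 = 222
  n_plates <- ceiling(nrow(library) / per_plate)

  all_wells <- as.vector(outer(.plate_rows, 1:24, paste0))
  purrr::map_dfr(seq_len(n_plates), function(p) {
    ids <- library$compound_id[((p - 1) * per_plate + 1):min(p * per_plate, nrow(library))]
    w <- tibble(plate_id = sprintf("P%02d", p), well = all_wells)
    w$role <- "buffer"
    w$role[w$well %in% inner] <- "empty"
    w$role[w$well %in% ctl$dmso_control] <- "dmso_control"
    w$role[w$well %in% ctl$pos_control] <- "pos_control"
    used <- cpd_wells[seq_along(ids)]
    w$role[match(used, w$well)] <- "compound"
    w$compound_id <- NA_character_
    w$compound_id[match(used, w$well)] <- ids
    w$row <- substr(w$well, 1, 1)
    w$col <- as.integer(substring(w$well, 2))
    w[order(w$col, w$row), c("plate_id", "well", "row", "col", "role", "compound_id")]
  })
}
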