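#' Plate formats
#'
#' A plate format is the rectangular pinning grid of an arrayed agar plate.
#' The named densities follow the standard colony-array series: 96 = 8 x 12,
#' 384 = 16 x 24, 1536 = 32 x 48. Coordinates everywhere in this package are
#' 0-based `(row, col)` with row 0 at the top-left, matching image row-major
#' order.
#'
#' @param density Either a named density (96, 384 or 1536) or a length-2
#'   integer vector `c(rows, cols)`.
#' @return An object of class `plate_format`: a list with elements `rows` and
#'   `cols`.
#' @examples
#' plate_format(1536)
#' plate_format(c(4, 6))
#' @export
plate_format <- function(density) {
  if (length(density) == 1) {
    density <- as.integer(density)
    dims <- switch(as.character(density),
      "96"   = c(8L, 12L),
      "384"  = c(16L, 24L),
      "1536" = c(32L, 48L),
      stop("unknown named plate format: ", density,
           " (use 96, 384, 1536 or c(rows, cols))")
    )
  } else if (length(density) == 2) {
    dims <- as.integer(density)
  } else {
    stop("`density` must be a named format or c(rows, cols)")
  }
  if (any(is.na(dims)) || any(dims < 1)) stop("rows and cols must be >= 1")
  structure(list(rows = dims[1], cols = dims[2]), class = "plate_format")
}

#' @export
print.plate_format <- function(x, ...) {
  cat(sprintf("<plate_format %d x %d (%d positions)>\n",
              x$rows, x$cols, x$rows * x$cols))
  invisible(x)
}

#' Position roles on a mating plate
#'
#' Every pinned position carries exactly one role:
#' \describe{
#'   \item{experimental_mating}{a library donor strain pinned together with
#'     the fixed recipient; the object of the screen.}
#'   \item{control_mating}{the genetically identical reference mating
#'     (control donor x recipient) interleaved across the plate; the local
#'     normalization reference.}
#'   \item{donor_only}{a donor pinned without recipient; negative growth
#'     control on the doubly selective medium.}
#'   \item{recipient_only}{the recipient pinned alone; negative control.}
#'   \item{positive_control}{a doubly resistant strain that grows with no
#'     lag; used in the platform test scheme.}
#'   \item{empty}{nothing deposited.}
#' }
#'
#' @return Character vector of the six role names.
#' @export
plate_roles <- function() {
  c("experimental_mating", "control_mating", "donor_only",
    "recipient_only", "positive_control", "empty")
}

# slot = (a, b) source-plate offset within the 4x4 pinning super-block of a
# 1536 plate: source well (r, c) of the slot lands at plate position
# (4 r + a, 4 c + b). Coordinate labels on pinning maps call this A1..D4
# (letter = a, number = b + 1).
slot_label <- function(a, b) paste0(LETTERS[a + 1], b + 1)

new_plate_layout <- function(format, positions) {
  positions <- positions[order(positions$row, positions$col), , drop = FALSE]
  rownames(positions) <- NULL
  structure(list(format = format, positions = positions),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout %d x %d>\n", x$format$rows, x$format$cols))
  print(count_by_role(x))
  invisible(x)
}

#' Build the interleaved-control screen layout
#'
#' Constructs the pinning layout of one screening plate: library donor
#' strains are pinned together with a fixed recipient as experimental
#' matings, the reference control mating occupies every fourth position (one
#' per 2 x 2 block, 384 of the 1,536 positions), and one column-slot group
#' carries the negative controls (each library donor alone, the control
#' donor alone, and the recipient alone).
#'
#' The 1536 grid is treated as an 8 x 12 super-grid of 4 x 4 blocks; each of
#' the 16 block-local offsets (a "slot", labelled A1..D4) receives one
#' 96-position source plate. Four slots hold controls, four hold negative
#' controls, and the remaining eight hold experimental strain plates at
#' `n_replicates_per_plate` replicates each.
#'
#' @param strain_plates List of character vectors, each a source plate of up
#'   to 96 strain identifiers in row-major 8 x 12 order. `NA` entries (and
#'   trailing absent wells) become empty positions.
#' @param format Plate format; the interleaved scheme requires 1536.
#' @param n_replicates_per_plate Replicates of every strain on this plate
#'   (consecutive slots per strain plate). Default 4, the moderate-
#'   replication screen design (two such plates give n = 8).
#' @param control_block_offset Block-local `(row, col)` index (each 0 or 1)
#'   of the control position inside every 2 x 2 block. Default `c(1, 1)`
#'   (odd row, odd col).
#' @param control_strain,recipient_strain Identifiers recorded for control
#'   matings and for the negative-control positions.
#' @return A `plate_layout`: format plus a data.frame with columns `row`,
#'   `col`, `role`, `strain`, `replicate`.
#' @examples
#' lay <- build_screen_layout(list(P1 = sprintf("s%02d", 1:96),
#'                                 P2 = sprintf("t%02d", 1:96)))
#' count_by_role(lay)
#' @export
build_screen_layout <- function(strain_plates,
                                format = plate_format(1536),
                                n_replicates_per_plate = 4,
                                control_block_offset = c(1, 1),
                                control_strain = "control",
                                recipient_strain = "recipient") {
  if (format$rows %% 4 != 0 || format$cols %% 4 != 0)
    stop("interleaved screen scheme needs rows and cols divisible by 4 ",
         "(1536 format)")
  if (!is.list(strain_plates)) strain_plates <- list(strain_plates)
  if (is.null(names(strain_plates)))
    names(strain_plates) <- paste0("P", seq_along(strain_plates))
  br <- control_block_offset[1]; bc <- control_block_offset[2]
  stopifnot(br %in% 0:1, bc %in% 0:1)

  ctl_a <- c(br, br + 2L); ctl_b <- c(bc, bc + 2L)
  neg_b <- setdiff(0:3, ctl_b)[order(setdiff(0:3, ctl_b))]
  # negative controls share the controls' row-parity, complementary col-parity
  neg_slots <- rbind(
    c(ctl_a[1], neg_b[1]), c(ctl_a[2], neg_b[1]),
    c(ctl_a[1], neg_b[2]), c(ctl_a[2], neg_b[2]))
  exp_a <- setdiff(0:3, ctl_a)
  exp_slots <- as.matrix(expand.grid(b = 0:3, a = exp_a))[, c("a", "b")]
  exp_slots <- exp_slots[order(exp_slots[, 1], exp_slots[, 2]), , drop = FALSE]

  n_needed <- length(strain_plates) * n_replicates_per_plate
  if (n_needed > nrow(exp_slots)) {
    overflow <- min(length(strain_plates),
                    nrow(exp_slots) %/% n_replicates_per_plate + 1L)
    stop(sprintf(
      "capacity exceeded: %d strain plates x %d replicates need %d slots, only %d available (strain plate '%s' does not fit)",
      length(strain_plates), n_replicates_per_plate, n_needed, nrow(exp_slots),
      names(strain_plates)[overflow]))
  }

  sb_rows <- format$rows %/% 4L; sb_cols <- format$cols %/% 4L
  n_wells <- sb_rows * sb_cols  # wells per source slot (96 on a 1536 plate)
  well <- expand.grid(c = 0:(sb_cols - 1), r = 0:(sb_rows - 1))

  slot_positions <- function(a, b, role, strains, replicate) {
    data.frame(row = 4L * well$r + a, col = 4L * well$c + b,
               role = role, strain = strains, replicate = replicate,
               stringsAsFactors = FALSE)
  }

  parts <- list()
  for (a in ctl_a) for (b in ctl_b)
    parts[[length(parts) + 1L]] <-
      slot_positions(a, b, "control_mating", control_strain, NA_integer_)
  slot_i <- 0L
  for (p in seq_along(strain_plates)) {
    strains <- as.character(strain_plates[[p]])
    if (length(strains) > n_wells)
      stop(sprintf("strain plate '%s' has %d strains; capacity is %d",
                   names(strain_plates)[p], length(strains), n_wells))
    strains <- c(strains, rep(NA_character_, n_wells - length(strains)))
    for (rep_i in seq_len(n_replicates_per_plate)) {
      slot_i <- slot_i + 1L
      a <- exp_slots[slot_i, 1]; b <- exp_slots[slot_i, 2]
      df <- slot_positions(a, b, "experimental_mating", strains, rep_i)
      df$role[is.na(df$strain)] <- "empty"
      parts[[length(parts) + 1L]] <- df
    }
  }
  # unused experimental slots stay empty
  if (slot_i < nrow(exp_slots)) {
    for (j in (slot_i + 1L):nrow(exp_slots)) {
      a <- exp_slots[j, 1]; b <- exp_slots[j, 2]
      parts[[length(parts) + 1L]] <-
        slot_positions(a, b, "empty", NA_character_, NA_integer_)
    }
  }
  # negative controls: donor-only per strain plate, control donor, recipient
  neg_roles <- c(rep("donor_only", length(strain_plates)),
                 "donor_only", "recipient_only")
  neg_strain <- c(paste0(names(strain_plates), "_donor"),
                  control_strain, recipient_strain)
  for (j in seq_len(nrow(neg_slots))) {
    role <- if (j <= length(neg_roles)) neg_roles[j] else "empty"
    strain <- if (j <= length(neg_roles)) neg_strain[j] else NA_character_
    parts[[length(parts) + 1L]] <-
      slot_positions(neg_slots[j, 1], neg_slots[j, 2], role, strain,
                     NA_integer_)
  }
  new_plate_layout(format, do.call(rbind, parts))
}

#' Build a plain layout with no interleaved controls
#'
#' Fills a plate row-major with one strain plate and no control positions;
#' the degenerate screen design used for simple growth assays.
#'
#' @param strains Character vector of strain identifiers, at most
#'   `rows * cols`.
#' @param format Plate format (default 96).
#' @return A `plate_layout` whose non-empty positions are all experimental
#'   matings, replicate 1.
#' @export
build_plain_layout <- function(strains, format = plate_format(96)) {
  n <- format$rows * format$cols
  if (length(strains) > n) stop("more strains than positions")
  strains <- c(as.character(strains), rep(NA_character_, n - length(strains)))
  pos <- expand.grid(col = 0:(format$cols - 1), row = 0:(format$rows - 1))
  df <- data.frame(row = pos$row, col = pos$col,
                   role = ifelse(is.na(strains), "empty", "experimental_mating"),
                   strain = strains, replicate = 1L, stringsAsFactors = FALSE)
  df$replicate[is.na(df$strain)] <- NA_integer_
  new_plate_layout(format, df)
}

#' Build the platform test layout
#'
#' The layout used to establish baseline parameters of the plate mating
#' assay: 768 identical control matings (donor x recipient) in the eight
#' even-row slots, the doubly resistant positive-control strain at every
#' fourth position, and donor-only / recipient-only negative controls.
#'
#' @inheritParams build_screen_layout
#' @param positive_strain Identifier for the doubly resistant positive
#'   control.
#' @return A `plate_layout`.
#' @export
build_test_layout <- function(format = plate_format(1536),
                              control_strain = "control",
                              recipient_strain = "recipient",
                              positive_strain = "positive") {
  if (format$rows %% 4 != 0 || format$cols %% 4 != 0)
    stop("test scheme needs rows and cols divisible by 4")
  pos <- expand.grid(col = 0:(format$cols - 1), row = 0:(format$rows - 1))
  a <- pos$row %% 4; b <- pos$col %% 4
  lab <- slot_label(a, b)
  role <- rep("empty", nrow(pos))
  strain <- rep(NA_character_, nrow(pos))
  mate <- lab %in% c("A1", "A2", "A3", "A4", "C1", "C2", "C3", "C4")
  role[mate] <- "control_mating"; strain[mate] <- control_strain
  posc <- lab %in% c("B2", "B4", "D2", "D4")
  role[posc] <- "positive_control"; strain[posc] <- positive_strain
  rec <- lab %in% c("B1", "D3")
  role[rec] <- "recipient_only"; strain[rec] <- recipient_strain
  don <- lab %in% c("B3", "D1")
  role[don] <- "donor_only"; strain[don] <- control_strain
  rep_id <- rep(NA_integer_, nrow(pos))
  rep_id[mate] <- match(lab[mate], c("A1", "A2", "A3", "A4",
                                     "C1", "C2", "C3", "C4"))
  new_plate_layout(format, data.frame(
    row = pos$row, col = pos$col, role = role, strain = strain,
    replicate = rep_id, stringsAsFactors = FALSE))
}

#' Build the donor-library construction layout
#'
#' One mating position per 4 x 4 block (library strain x plasmid donor),
#' with the library strain alone and the donor alone as negative controls;
#' the remaining block positions are unused.
#'
#' @param strains Character vector of up to 96 library strain identifiers.
#' @param format Plate format (default 1536).
#' @param donor_strain Identifier of the plasmid-bearing donor.
#' @return A `plate_layout`.
#' @export
build_library_layout <- function(strains, format = plate_format(1536),
                                 donor_strain = "donor") {
  if (format$rows %% 4 != 0 || format$cols %% 4 != 0)
    stop("library construction scheme needs rows and cols divisible by 4")
  sb_rows <- format$rows %/% 4L; sb_cols <- format$cols %/% 4L
  n_wells <- sb_rows * sb_cols
  if (length(strains) > n_wells) stop("more strains than blocks")
  strains <- c(as.character(strains), rep(NA_character_,
                                          n_wells - length(strains)))
  pos <- expand.grid(col = 0:(format$cols - 1), row = 0:(format$rows - 1))
  a <- pos$row %% 4; b <- pos$col %% 4
  widx <- (pos$row %/% 4) * sb_cols + (pos$col %/% 4) + 1L
  s <- strains[widx]
  role <- rep("empty", nrow(pos))
  strain <- rep(NA_character_, nrow(pos))
  mate <- a == 0 & b == 0 & !is.na(s)          # slot A1: mating
  neg_r <- a == 2 & b == 1 & !is.na(s)         # slot C2: library strain alone
  neg_d <- a == 2 & b == 2 & !is.na(s)         # slot C3: donor alone
  role[mate] <- "experimental_mating"; strain[mate] <- s[mate]
  role[neg_r] <- "recipient_only";     strain[neg_r] <- s[neg_r]
  role[neg_d] <- "donor_only";         strain[neg_d] <- donor_strain
  new_plate_layout(format, data.frame(
    row = pos$row, col = pos$col, role = role, strain = strain,
    replicate = ifelse(mate, 1L, NA_integer_), stringsAsFactors = FALSE))
}

#' Count plate positions by role
#'
#' @param layout A `plate_layout`.
#' @return Named integer vector over all six roles; the counts sum to
#'   `rows * cols`.
#' @export
count_by_role <- function(layout) {
  stopifnot(inherits(layout, "plate_layout"))
  tab <- table(factor(layout$positions$role, levels = plate_roles()))
  stats::setNames(as.integer(tab), names(tab))
}

#' Nearest control positions
#'
#' Returns the `k` control-mating positions closest (Euclidean distance in
#' grid units) to a query position. Ties are broken by `(row, col)`
#' lexicographic order, so the result is deterministic.
#'
#' @param layout A `plate_layout`.
#' @param pos Length-2 vector `c(row, col)`, 0-based.
#' @param k Number of controls to return.
#' @param exclude_self Drop the query position itself from the candidates
#'   (used when normalizing a control against its neighbours).
#' @return A data.frame with columns `row`, `col`, `distance`, ordered by
#'   increasing distance then `(row, col)`.
#' @export
nearest_controls <- function(layout, pos, k = 4, exclude_self = FALSE) {
  stopifnot(inherits(layout, "plate_layout"), length(pos) == 2)
  ctl <- layout$positions[layout$positions$role == "control_mating",
                          c("row", "col")]
  if (exclude_self)
    ctl <- ctl[!(ctl$row == pos[1] & ctl$col == pos[2]), , drop = FALSE]
  if (nrow(ctl) < k)
    stop(sprintf("layout has %d eligible control positions; %d requested",
                 nrow(ctl), k))
  d <- sqrt((ctl$row - pos[1])^2 + (ctl$col - pos[2])^2)
  ord <- order(d, ctl$row, ctl$col)[seq_len(k)]
  data.frame(row = ctl$row[ord], col = ctl$col[ord], distance = d[ord])
}

#' Precompute the nearest-control map of a layout
#'
#' For every plate position, finds the indices (into the control subset) of
#' its `k` nearest control matings, leaving a control out of its own
#' neighbourhood. Used to vectorize local-reference computation over whole
#' plates.
#'
#' @param layout A `plate_layout`.
#' @param k Controls per neighbourhood.
#' @param valid Optional logical vector over the layout's control positions
#'   (in `(row, col)` order): controls marked `FALSE` (e.g. failed QC) are
#'   skipped when choosing neighbours.
#' @return A list with `controls` (data.frame of control positions, in
#'   `(row, col)` order) and `neighbour_index` (n_positions x k integer
#'   matrix indexing into `controls`, rows in the layout's row-major
#'   position order).
#' @export
control_neighbour_map <- function(layout, k = 4, valid = NULL) {
  p <- layout$positions
  ctl <- which(p$role == "control_mating")
  cr <- p$row[ctl]; cc <- p$col[ctl]
  if (is.null(valid)) valid <- rep(TRUE, length(ctl))
  stopifnot(length(valid) == length(ctl))
  if (sum(valid) < k + 1)
    stop("layout needs more than k valid control positions")
  n <- nrow(p)
  idx <- matrix(NA_integer_, n, k)
  # distance matrix positions x controls; fine at 1536 x 384
  d2 <- outer(p$row, cr, `-`)^2 + outer(p$col, cc, `-`)^2
  d2[, !valid] <- Inf
  is_ctl_row <- p$role == "control_mating"
  for (i in seq_len(n)) {
    di <- d2[i, ]
    if (is_ctl_row[i]) di[p$row[ctl] == p$row[i] & p$col[ctl] == p$col[i]] <- Inf
    ord <- order(di, cr, cc)
    idx[i, ] <- ord[seq_len(k)]
  }
  list(controls = data.frame(row = cr, col = cc, pos_index = ctl),
       neighbour_index = idx)
}

#' Write / read a layout as a flat delimited table
#'
#' The on-disk form is a tab-separated table with header
#' `row  col  role  strain  replicate` in 0-based row-major order.
#'
#' @param layout A `plate_layout`.
#' @param path File path.
#' @return `read_layout` returns a `plate_layout`; `write_layout` returns
#'   `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  utils::write.table(layout$positions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "role", "strain", "replicate")
  if (!all(need %in% names(df)))
    stop("layout table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$role %in% plate_roles()))
    stop("unknown role in layout table")
  fmt <- plate_format(c(max(df$row) + 1L, max(df$col) + 1L))
  if (nrow(df) != fmt$rows * fmt$cols)
    stop("layout table does not cover the full grid")
  new_plate_layout(fmt, df)
}

#' Build a screen layout from a key-value config file
#'
#' The config is YAML with keys `format` (named density), `control_scheme`
#' (`interleaved` or `none`), optionally `control_block_offset` (two 0/1
#' integers), `n_replicates_per_plate`, and `strain_plates`: a mapping from
#' source-plate name to its strain list.
#'
#' @param path Path to the YAML config.
#' @return A `plate_layout`.
#' @export
read_layout_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fmt <- plate_format(cfg$format)
  scheme <- if (is.null(cfg$control_scheme)) "interleaved" else cfg$control_scheme
  if (scheme == "none")
    return(build_plain_layout(unlist(cfg$strain_plates, use.names = FALSE),
                              format = fmt))
  off <- if (is.null(cfg$control_block_offset)) c(1, 1) else
    as.integer(cfg$control_block_offset)
  nrep <- if (is.null(cfg$n_replicates_per_plate)) 4 else
    cfg$n_replicates_per_plate
  build_screen_layout(lapply(cfg$strain_plates, as.character), format = fmt,
                      n_replicates_per_plate = nrep,
                      control_block_offset = off)
}
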