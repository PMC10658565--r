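# Crystal-lattice density metrics: unit-cell volume, Matthews coefficient,
# solvent content, and density ranking of polymorphic crystal forms.

#' Construct a unit cell
#'
#' A triclinic unit cell is described by three edge lengths (Angstrom) and
#' three inter-axial angles (degrees). The constructor checks that the cell is
#' geometrically realizable, i.e. that the metric-tensor determinant is
#' strictly positive.
#'
#' @param a,b,c Edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees; must lie in
#'   (0, 180).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(31.468, 39.369, 39.952, 102.140, 90.231, 90.948)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("unit cell edge lengths must be positive and finite", call. = FALSE)
  if (any(!is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("unit cell angles must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  cell <- structure(list(a = a, b = b, c = c,
                         alpha = alpha, beta = beta, gamma = gamma),
                    class = "unit_cell")
  if (.cell_radicand(cell) <= 0)
    stop("unit cell is not geometrically realizable ",
         "(metric-tensor determinant is not positive)", call. = FALSE)
  cell
}

# radicand of the triclinic volume closed form; equals det(G)/(abc)^2
.cell_radicand <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
}

#' Unit-cell volume
#'
#' Evaluates the standard triclinic closed form
#' \deqn{V = abc\sqrt{1-\cos^2\alpha-\cos^2\beta-\cos^2\gamma
#'   + 2\cos\alpha\cos\beta\cos\gamma}.}
#' For an orthorhombic cell (all angles 90 degrees) this reduces exactly to
#' \eqn{abc}.
#'
#' @param cell A [unit_cell()].
#' @return Cell volume in cubic Angstrom.
#' @examples
#' cell_volume(unit_cell(10, 10, 10))              # 1000
#' cell_volume(unit_cell(31.220, 41.090, 74.050))  # orthorhombic a*b*c
#' @export
cell_volume <- function(cell) {
  if (!inherits(cell, "unit_cell")) cell <- do.call(unit_cell, as.list(cell))
  rad <- .cell_radicand(cell)
  if (rad <= 0)
    stop("unit cell is not geometrically realizable (radicand <= 0)",
         call. = FALSE)
  cell$a * cell$b * cell$c * sqrt(rad)
}

# Space-group multiplicities for the common Sohncke groups encountered in
# protein crystallography. Symbols are stored in normalized form (no spaces,
# no parentheses/underscores, upper case lattice letter).
.SPACE_GROUPS <- c(
  "P1" = 1L,
  "P2" = 2L, "P21" = 2L, "C2" = 4L,
  "P222" = 4L, "P2221" = 4L, "P21212" = 4L, "P212121" = 4L,
  "C222" = 8L, "C2221" = 8L, "I222" = 8L, "I212121" = 8L, "F222" = 16L,
  "P4" = 4L, "P41" = 4L, "P42" = 4L, "P43" = 4L, "I4" = 8L, "I41" = 8L,
  "P422" = 8L, "P4212" = 8L, "P4122" = 8L, "P41212" = 8L,
  "P4222" = 8L, "P42212" = 8L, "P4322" = 8L, "P43212" = 8L,
  "I422" = 16L, "I4122" = 16L,
  "P3" = 3L, "P31" = 3L, "P32" = 3L, "R3" = 9L,
  "P312" = 6L, "P321" = 6L, "P3112" = 6L, "P3121" = 6L,
  "P3212" = 6L, "P3221" = 6L, "R32" = 18L,
  "P6" = 6L, "P61" = 6L, "P65" = 6L, "P62" = 6L, "P64" = 6L, "P63" = 6L,
  "P622" = 12L, "P6122" = 12L, "P6522" = 12L, "P6222" = 12L,
  "P6422" = 12L, "P6322" = 12L,
  "P23" = 12L, "F23" = 48L, "I23" = 12L, "P213" = 12L, "I213" = 24L,
  "P432" = 24L, "P4232" = 24L, "F432" = 96L, "F4132" = 96L,
  "I432" = 48L, "P4332" = 24L, "P4132" = 24L, "I4132" = 48L
)

#' Normalize a Hermann-Mauguin space-group symbol
#'
#' Collapses the whitespace, parenthesis and subscript-underscore variants
#' seen in headers and tables ("P 21 21 21", "P2(1)2(1)2(1)",
#' "P2_1_2_1_2_1_") onto one canonical spelling ("P212121").
#'
#' @param symbol Character space-group symbol.
#' @return Normalized symbol string.
#' @export
normalize_space_group <- function(symbol) {
  s <- gsub("[ _()]", "", as.character(symbol))
  paste0(toupper(substr(s, 1, 1)), substring(s, 2))
}

#' Space-group symmetry information
#'
#' Looks up the general-position multiplicity (symmetry-equivalent copies per
#' unit cell) of a space group from a built-in table of the common Sohncke
#' groups. Unknown symbols fail loudly rather than guessing.
#'
#' @param symbol Hermann-Mauguin symbol in any of the accepted spelling
#'   variants (see [normalize_space_group()]).
#' @return An object of class `space_group` with elements `symbol`
#'   (normalized) and `multiplicity`.
#' @examples
#' space_group("P1")$multiplicity         # 1
#' space_group("P2(1)2(1)2(1)")$multiplicity  # 4
#' @export
space_group <- function(symbol) {
  norm <- normalize_space_group(symbol)
  if (!norm %in% names(.SPACE_GROUPS))
    stop("unknown space-group symbol: '", symbol, "' (normalized '",
         norm, "')", call. = FALSE)
  structure(list(symbol = norm,
                 multiplicity = unname(.SPACE_GROUPS[norm])),
            class = "space_group")
}

#' Construct a crystal-form record
#'
#' One crystal polymorph: its unit cell, space group, number of protein
#' copies in the asymmetric unit, and protein molar mass. Ion and ordered
#' solvent mass (sulfate, zinc) is excluded from `molar_mass` by default;
#' the tabulated Matthews coefficients are reproducible without it.
#'
#' @param name Label for the form.
#' @param cell A [unit_cell()].
#' @param space_group A [space_group()] or a symbol string.
#' @param copies_per_asu Protein copies per asymmetric unit (>= 1).
#' @param molar_mass Protein molar mass in Da (> 0), or `NA` if it is to be
#'   back-filled with [infer_molar_mass()].
#' @param partial_specific_volume Protein partial specific volume in cm^3/g;
#'   defaults to the conventional 0.74.
#' @return An object of class `crystal_form`.
#' @export
crystal_form <- function(name, cell, space_group, copies_per_asu,
                         molar_mass = NA_real_,
                         partial_specific_volume = 0.74) {
  if (!inherits(cell, "unit_cell")) stop("cell must be a unit_cell")
  if (is.character(space_group)) space_group <- space_group(space_group)
  if (!inherits(space_group, "space_group"))
    stop("space_group must be a space_group object or symbol string")
  copies_per_asu <- as.integer(copies_per_asu)
  if (is.na(copies_per_asu) || copies_per_asu < 1L)
    stop("copies_per_asu must be an integer >= 1", call. = FALSE)
  if (!is.na(molar_mass) && molar_mass <= 0)
    stop("molar_mass must be positive", call. = FALSE)
  if (partial_specific_volume <= 0)
    stop("partial_specific_volume must be positive", call. = FALSE)
  structure(list(name = as.character(name), cell = cell,
                 space_group = space_group,
                 copies_per_asu = copies_per_asu,
                 molar_mass = as.numeric(molar_mass),
                 partial_specific_volume = partial_specific_volume),
            class = "crystal_form")
}

#' Matthews coefficient
#'
#' Crystal volume per Dalton of protein,
#' \eqn{V_M = V_{cell} / (Z \cdot n_{asu} \cdot M)}, where Z is the
#' space-group multiplicity, n_asu the copies per asymmetric unit and M the
#' protein molar mass. Lower values mean denser packing.
#'
#' @param form A [crystal_form()] with a known molar mass.
#' @param cell_volume Cell volume in Angstrom^3; computed from `form$cell`
#'   when omitted.
#' @return V_M in Angstrom^3 per Dalton.
#' @export
matthews_coefficient <- function(form, cell_volume = NULL) {
  if (is.null(cell_volume)) cell_volume <- cell_volume(form$cell)
  if (cell_volume <= 0) stop("cell_volume must be positive", call. = FALSE)
  if (is.na(form$molar_mass) || form$molar_mass <= 0)
    stop("crystal form needs a positive molar mass ",
         "(use infer_molar_mass to back-fill)", call. = FALSE)
  cell_volume /
    (form$space_group$multiplicity * form$copies_per_asu * form$molar_mass)
}

#' Infer protein molar mass from a Matthews coefficient
#'
#' Algebraic inverse of [matthews_coefficient()], used to back-fill fixture
#' molar masses from tabulated cell volumes and Matthews coefficients:
#' \eqn{M = V_{cell} / (Z \cdot n_{asu} \cdot V_M)}.
#'
#' @param form A [crystal_form()] (its molar mass is ignored).
#' @param cell_volume Cell volume, Angstrom^3; computed from the form's cell
#'   when omitted.
#' @param matthews Target Matthews coefficient, Angstrom^3/Da (> 0).
#' @return Molar mass in Da.
#' @export
infer_molar_mass <- function(form, matthews, cell_volume = NULL) {
  if (is.null(cell_volume)) cell_volume <- cell_volume(form$cell)
  if (matthews <= 0) stop("matthews must be positive", call. = FALSE)
  z <- form$space_group$multiplicity * form$copies_per_asu
  if (z < 1) stop("multiplicity and copies_per_asu must be >= 1",
                  call. = FALSE)
  cell_volume / (z * matthews)
}

#' Solvent fraction from the Matthews coefficient
#'
#' The fraction of the crystal occupied by solvent:
#' \deqn{f_{solv} = 1 - \frac{\bar v / 0.6022}{V_M}}
#' with \eqn{\bar v} the protein partial specific volume in cm^3/g and
#' 0.6022 the unit-bridging constant (Avogadro's number scaled to
#' Angstrom^3 Da cm^-3 g). A V_M at or below the protein-only limit
#' \eqn{\bar v / 0.6022} is reported as 0 with a warning flag rather than a
#' negative fraction.
#'
#' @param matthews Matthews coefficient V_M, Angstrom^3/Da.
#' @param partial_specific_volume Partial specific volume, cm^3/g
#'   (default 0.74).
#' @return Solvent fraction in `[0, 1)`; attribute `overfilled` is `TRUE`
#'   when the protein-only limit was hit.
#' @examples
#' solvent_fraction(1.76)  # ~0.302, i.e. ~30% solvent
#' @export
solvent_fraction <- function(matthews, partial_specific_volume = 0.74) {
  if (matthews <= 0) stop("matthews must be positive", call. = FALSE)
  frac <- 1 - (partial_specific_volume / 0.6022) / matthews
  if (frac <= 0) {
    warning("Matthews coefficient at or below the protein-only limit; ",
            "solvent fraction reported as 0")
    return(structure(0, overfilled = TRUE))
  }
  structure(frac, overfilled = FALSE)
}

#' Per-form lattice density report
#'
#' @param form A [crystal_form()].
#' @return A list of class `lattice_density_report` with `name`,
#'   `cell_volume`, `matthews`, `solvent_fraction` and `protein_fraction`
#'   (the two fractions sum to exactly 1).
#' @export
lattice_density_report <- function(form) {
  v <- cell_volume(form$cell)
  vm <- matthews_coefficient(form, v)
  sf <- solvent_fraction(vm, form$partial_specific_volume)
  structure(list(name = form$name, cell_volume = v, matthews = vm,
                 solvent_fraction = as.numeric(sf),
                 protein_fraction = 1 - as.numeric(sf),
                 overfilled = isTRUE(attr(sf, "overfilled"))),
            class = "lattice_density_report")
}

#' Rank crystal forms by packing density
#'
#' Stable ascending sort by solvent fraction (densest first); ties broken by
#' Matthews coefficient, then by name.
#'
#' @param reports List of [lattice_density_report()] objects (length >= 2).
#' @return The reports reordered densest-first; each gains a `rank` element.
#' @export
rank_density <- function(reports) {
  if (length(reports) < 2)
    stop("rank_density needs at least two reports", call. = FALSE)
  sf <- vapply(reports, `[[`, numeric(1), "solvent_fraction")
  vm <- vapply(reports, `[[`, numeric(1), "matthews")
  nm <- vapply(reports, `[[`, character(1), "name")
  ord <- order(sf, vm, nm)
  out <- reports[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' Tabulate lattice density reports
#'
#' Builds the exchange table `name, cell_volume_A3, matthews_A3_per_Da,
#' solvent_pct, rank`. Percentages mimic the conventional table style:
#' solvent content is carried unrounded in `solvent_frac` and rounded to two
#' decimals in `solvent_pct`.
#'
#' @param forms List of [crystal_form()] objects.
#' @return A data.frame, one row per form, ranked densest-first.
#' @export
lattice_report_table <- function(forms) {
  reports <- rank_density(lapply(forms, lattice_density_report))
  data.frame(
    name = vapply(reports, `[[`, character(1), "name"),
    cell_volume_A3 = vapply(reports, `[[`, numeric(1), "cell_volume"),
    matthews_A3_per_Da = vapply(reports, `[[`, numeric(1), "matthews"),
    solvent_frac = vapply(reports, `[[`, numeric(1), "solvent_fraction"),
    solvent_pct = round(100 * vapply(reports, `[[`, numeric(1),
                                     "solvent_fraction"), 2),
    rank = vapply(reports, `[[`, integer(1), "rank"),
    stringsAsFactors = FALSE
  )
}

# ---- record readers ---------------------------------------------------------

# CRYST1 fixed columns (PDB format v3.3):
# a 7-15, b 16-24, c 25-33, alpha 34-40, beta 41-47, gamma 48-54, sg 56-66
.parse_cryst1 <- function(line) {
  if (nchar(line) < 54)
    stop("malformed CRYST1 record (too short): '", line, "'", call. = FALSE)
  num <- function(from, to) {
    x <- suppressWarnings(as.numeric(substr(line, from, to)))
    if (is.na(x))
      stop("malformed CRYST1 record: non-numeric field in columns ",
           from, "-", to, call. = FALSE)
    x
  }
  cell <- unit_cell(num(7, 15), num(16, 24), num(25, 33),
                    num(34, 40), num(41, 47), num(48, 54))
  sg <- trimws(substr(line, 56, min(66, nchar(line))))
  if (!nzchar(sg)) stop("CRYST1 record has no space-group field",
                        call. = FALSE)
  list(cell = cell, space_group = space_group(sg))
}

# minimal mmCIF scan: only _cell.length_*, _cell.angle_* and the H-M symbol.
.parse_mmcif_cell <- function(lines) {
  grab <- function(key) {
    hit <- grep(paste0("^\\s*", key, "\\s"), lines, value = TRUE)
    if (!length(hit))
      stop("mmCIF source lacks field ", key, call. = FALSE)
    val <- trimws(sub(paste0("^\\s*", key, "\\s+"), "", hit[[1]]))
    gsub("^['\"]|['\"]$", "", val)
  }
  cell <- unit_cell(as.numeric(grab("_cell\\.length_a")),
                    as.numeric(grab("_cell\\.length_b")),
                    as.numeric(grab("_cell\\.length_c")),
                    as.numeric(grab("_cell\\.angle_alpha")),
                    as.numeric(grab("_cell\\.angle_beta")),
                    as.numeric(grab("_cell\\.angle_gamma")))
  sym <- tryCatch(grab("_symmetry\\.space_group_name_H-M"),
                  error = function(e)
                    grab("_space_group\\.name_H-M_alt"))
  list(cell = cell, space_group = space_group(sym))
}

#' Read a unit cell and space group from a header record
#'
#' Accepts one of three dialects: a PDB `CRYST1` fixed-column line, a minimal
#' mmCIF fragment carrying `_cell.length_*`, `_cell.angle_*` and the
#' Hermann-Mauguin symbol, or a one-row CSV with header
#' `name,a,b,c,alpha,beta,gamma,space_group,copies,molar_mass_da` (in which
#' case a full [crystal_form()] is returned). The dialect is detected from
#' the content.
#'
#' @param source Path to a file, or a character vector of lines.
#' @return For CRYST1/mmCIF: list with `cell` and `space_group`. For CSV: a
#'   list of [crystal_form()] objects (one per row).
#' @export
read_cell_record <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  if (any(grepl("^CRYST1", lines)))
    return(.parse_cryst1(grep("^CRYST1", lines, value = TRUE)[[1]]))
  if (any(grepl("^\\s*_cell\\.length_a\\s", lines)))
    return(.parse_mmcif_cell(lines))
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("name", "a", "b", "c", "alpha", "beta", "gamma",
            "space_group", "copies")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CSV cell table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    crystal_form(
      name = r$name,
      cell = unit_cell(r$a, r$b, r$c, r$alpha, r$beta, r$gamma),
      space_group = space_group(r$space_group),
      copies_per_asu = r$copies,
      molar_mass = if ("molar_mass_da" %in% names(df))
        r$molar_mass_da else NA_real_
    )
  })
}

#' Write crystal forms to the CSV exchange dialect
#'
#' @param forms List of [crystal_form()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_csv <- function(forms, path) {
  df <- do.call(rbind, lapply(forms, function(f) {
    data.frame(name = f$name, a = f$cell$a, b = f$cell$b, c = f$cell$c,
               alpha = f$cell$alpha, beta = f$cell$beta,
               gamma = f$cell$gamma, space_group = f$space_group$symbol,
               copies = f$copies_per_asu, molar_mass_da = f$molar_mass,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
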