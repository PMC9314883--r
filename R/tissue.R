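# Tissue label dictionary and dielectric/density property table.

#' Tissue label dictionary
#'
#' The nine output classes of the segmentation network: eight tissue types
#' (internal air, bone, muscle, fat, white matter, gray matter,
#' cerebrospinal fluid, eye) plus background. Codes 0--8 are a fixed
#' bijection onto the names, with background = 0.
#'
#' @return A data.frame with columns `code` (integer 0--8) and `name`.
#' @export
#' @examples
#' tissue_labels()
tissue_labels <- function() {
  data.frame(
    code = 0:8,
    name = c("background", "internal_air", "bone", "muscle", "fat",
             "white_matter", "gray_matter", "csf", "eye"),
    stringsAsFactors = FALSE
  )
}

#' Map tissue names to codes
#' @param name Character vector of tissue names.
#' @return Integer codes.
#' @export
tissue_code <- function(name) {
  tl <- tissue_labels()
  i <- match(name, tl$name)
  if (anyNA(i)) stop("unknown tissue name: ", paste(name[is.na(i)], collapse = ", "))
  tl$code[i]
}

#' Map tissue codes to names
#' @param code Integer vector of tissue codes 0--8.
#' @return Character names.
#' @export
tissue_name <- function(code) {
  tl <- tissue_labels()
  i <- match(code, tl$code)
  if (anyNA(i)) stop("unknown tissue code: ", paste(code[is.na(i)], collapse = ", "))
  tl$name[i]
}

#' Default tissue dielectric and density properties at 300 MHz
#'
#' Literature-style values (IT'IS/Gabriel family) for conductivity (S/m),
#' relative permittivity and mass density (kg/m^3) at 300 MHz (7T proton
#' frequency). Background and internal air are non-conducting; internal air
#' additionally contributes no mass to averaging regions. The table is an
#' editable configuration (see [read_tissue_properties()]), not a constant
#' the dosimetry depends on.
#'
#' @return data.frame with columns `code`, `name`, `sigma`, `eps_r`, `rho`.
#' @export
default_tissue_properties <- function() {
  tl <- tissue_labels()
  props <- data.frame(
    name  = c("background", "internal_air", "bone", "muscle", "fat",
              "white_matter", "gray_matter", "csf", "eye"),
    sigma = c(0,    0,     0.083, 0.770, 0.037, 0.413, 0.692, 2.224, 1.517),
    eps_r = c(1,    1,     13.4,  58.2,  5.6,   43.8,  60.0,  72.7,  69.0),
    rho   = c(0,    1.2,   1908,  1090,  911,   1041,  1045,  1007,  1005),
    stringsAsFactors = FALSE
  )
  merge(tl, props, by = "name", sort = FALSE)[, c("code", "name", "sigma", "eps_r", "rho")]
}

validate_tissue_properties <- function(props) {
  need <- c("code", "name", "sigma", "eps_r", "rho")
  if (!all(need %in% names(props))) {
    stop("tissue property table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(props$sigma < 0)) stop("conductivity must be non-negative")
  tiss <- props$name %in% setdiff(tissue_labels()$name, c("background", "internal_air"))
  if (any(props$rho[tiss] <= 0)) stop("tissue density must be positive")
  if (any(props$sigma[props$name %in% c("background", "internal_air")] != 0)) {
    stop("background and internal_air must have zero conductivity")
  }
  invisible(props)
}

#' Read / write a tissue property table as YAML
#'
#' @param path File path.
#' @return `read_tissue_properties` returns the validated data.frame.
#' @export
read_tissue_properties <- function(path) {
  y <- yaml::read_yaml(path)
  props <- do.call(rbind, lapply(y$tissues, function(t) {
    data.frame(name = t$name, sigma = t$sigma, eps_r = t$eps_r, rho = t$rho,
               stringsAsFactors = FALSE)
  }))
  props$code <- tissue_code(props$name)
  validate_tissue_properties(props[, c("code", "name", "sigma", "eps_r", "rho")])
}

#' @rdname read_tissue_properties
#' @param props Property table as from [default_tissue_properties()].
#' @export
write_tissue_properties <- function(props, path) {
  validate_tissue_properties(props)
  y <- list(tissues = lapply(seq_len(nrow(props)), function(i) {
    list(name = props$name[i], sigma = props$sigma[i],
         eps_r = props$eps_r[i], rho = props$rho[i])
  }))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Default T1w-like mean intensities per tissue
#'
#' Relative signal levels used by [simulate_t1w()]: bright fat and white
#' matter, intermediate gray matter and muscle, dark bone/CSF/air, as in
#' MP-RAGE contrast. Arbitrary units.
#' @return Named numeric vector indexed by tissue name.
#' @export
default_t1w_means <- function() {
  c(background = 0.02, internal_air = 0.05, bone = 0.22, muscle = 0.55,
    fat = 1.20, white_matter = 1.00, gray_matter = 0.68, csf = 0.30,
    eye = 0.35)
}
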