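# Structured configuration: material, fibre-angle and solver settings read
# from / written to YAML.

#' Default configuration
#'
#' All tunable quantities with units: material scales (kPa), exponential
#' rates (dimensionless), bulk modulus (kPa), the ln J coefficient, valve
#' collagen constants, fibre angles (degrees) and solver settings.
#' @export
default_config <- function() {
  list(
    material = list(a0 = 0.24, af = 0.65, b0 = 5, bf = 5, K = 1000, k_log = 1,
                    c1 = 0.1, c2 = 0.5),
    fibres = list(lv_epi_deg = -60, lv_endo_deg = 60,
                  rv_epi_deg = -25, rv_endo_deg = 90,
                  ring_angles = list(mv = 0, av = 0, tv = 0, pv = 0),
                  ring_blend_mm = 5),
    qc = list(island_px = 50, lowpass_cycles = 10, dice_reject = 0.5,
              rv_epi_offset_mm = 3),
    solver = list(newton_tol = 1e-7, max_newton_iters = 150,
                  n_load_steps = 5, max_step_mm = 2),
    geometry = list(preset = "healthy", h = 3.5),
    sweep = list(gamma_min = 0.1, gamma_max = 1.0, gamma_step = 0.05))
}

#' Read a configuration file (YAML), filling unset keys with defaults
#' @param path YAML file.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  def <- default_config()
  for (sec in names(usr))
    def[[sec]][names(usr[[sec]])] <- usr[[sec]]
  def
}

#' Write a configuration file
#' @param cfg configuration list. @param path output YAML.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Materials from a configuration
#' @param cfg configuration list.
#' @export
config_materials <- function(cfg) {
  m <- cfg$material
  list(params = material_params(m$a0, m$af, m$b0, m$bf, m$K, m$k_log),
       valve = valve_material(m$c1, m$c2))
}

#' Angle specification from a configuration
#' @param cfg configuration list.
#' @export
config_angles <- function(cfg) {
  f <- cfg$fibres
  angle_spec(f$lv_epi_deg, f$lv_endo_deg, f$rv_epi_deg, f$rv_endo_deg,
             f$ring_angles, f$ring_blend_mm)
}
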