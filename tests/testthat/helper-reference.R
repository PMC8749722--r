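# Reference operating point and architecture shared across tests: the
# implemented 1 mm^2 device (4 SPADs/microcell, 16 subpixels, 512 um^2
# active area, yield 77%).
ref_op <- function(...) operating_conditions(...)
ref_budget <- function(...) area_budget(...)
ref_arch <- function() architecture(n_uc = 4, m_spl = 16, a_aspad = 512)

# Deterministic DCR population with an exactly known defective fraction:
# plateau at 50 Hz, defects at 100 kHz, f = n_def / n.
det_pop <- function(n = 2000, f = 0.10, plateau = 50, defect = 1e5,
                    a_aspad = 200) {
  n_def <- round(f * n)
  dcr_population(c(rep(plateau, n - n_def), rep(defect, n_def)),
                 a_aspad = a_aspad)
}
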