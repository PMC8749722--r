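# Reference operating point of the implemented digital SiPM
# (110 nm CIS technology) used for the architectural exploration.
# Areas in mm^2, times in seconds, photon density per mm^2.
a_pxl_mm2: 1.0
a_tdc_mm2: 6.5e-3
a_fsm_mm2: 14.0e-3
a_cnt_mm2: 2.6e-3
a_qrc_mm2: 72.0e-6
a_sram_mm2: 18.0e-6
a_rm_mm2: 205.0e-6
# dead-frame width of the SPAD footprint model, um; calibrated once with
# calibrate_guard_width() so the 1 mm^2 reference pixel holds 762 SPADs
guard_width_um: 5.184646
pdp: 0.30
d_ph_per_mm2: 450.0
t_pulse_s: 800.0e-12
t_clk_s: 20.0e-9
tau_sct_s: 40.0e-9
# SPAD dead time (DCR characterization conditions)
t_dead_s: 5.0e-6
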