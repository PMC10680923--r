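# Documented link-mass estimates for the carbon-fiber build; used only for
# feasibility margins, never for calibration targets.
proximal_link_mass_kg: 0.25
distal_link_mass_kg: 0.15
platform_mass_kg: 0.8
gonio_link1_mass_kg: 0.5
gonio_link2_mass_kg: 0.5
gonio_link3_mass_kg: 0.5
payload_mass_kg: 1.5
payload_yaw_inertia_kgm2: 0.002
gravity_m_s2: 9.81
distal_mass_split: 0.5
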