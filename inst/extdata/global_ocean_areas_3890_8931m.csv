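# Published per-basin area table for the 3890-8931 m depth envelope:
# suitable area (GEBCO_2023 bathymetry reclassified by depth, Global
# Oceans and Seas basin boundaries, equal-area measurement) and total
# ocean area, both in km^2.  Used to verify the package's percentage
# arithmetic against the published cells.
basin,envelope_area_km2,total_area_km2
Pacific,104575622,140274790.80
Atlantic,47677056.41,82348325.50
Indian,39622525.03,70834789.42
Southern,8443960.06,29594289.41
Arctic,564328.79,11880270.28
Mediterranean,28810.49,2988248.07
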