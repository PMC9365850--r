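# Example column map: logical field -> header used by a particular export.
island_id: "Island ID"
island_name: "Island Name"
country: "Country ISO"
area_ha: "Area (ha)"
target_species: "Species Common/Scientific"
status: "Eradication Status"
end_year: "End Year"
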