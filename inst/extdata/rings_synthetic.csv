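"species_id","ring"
"eurimedia_sp01","eurimedia"
"eurimedia_sp02","eurimedia"
"eurimedia_sp03","eurimedia"
"eurimedia_sp04","eurimedia"
"eurimedia_sp05","eurimedia"
"eurimedia_sp06","eurimedia"
"eurimedia_sp07","eurimedia"
"eurimedia_sp08","eurimedia"
"eurimedia_sp09","eurimedia"
"eurimedia_sp10","eurimedia"
"eurimedia_sp11","eurimedia"
"eurimedia_sp12","eurimedia"
"eurimedia_sp13","eurimedia"
"lerida_sp01","lerida"
"lerida_sp02","lerida"
"lerida_sp03","lerida"
"lerida_sp04","lerida"
"lerida_sp05","lerida"
"lerida_sp06","lerida"
"lerida_sp07","lerida"
"lerida_sp08","lerida"
"lerida_sp09","lerida"
"lerida_sp10","lerida"
"panthyale_sp01","panthyale"
"panthyale_sp02","panthyale"
"panthyale_sp03","panthyale"
"panthyale_sp04","panthyale"
"panthyale_sp05","panthyale"
"panthyale_sp06","panthyale"
"panthyale_sp07","panthyale"
"panthyale_sp08","panthyale"
"agnosia_sp01","agnosia"
"agnosia_sp02","agnosia"
"agnosia_sp03","agnosia"
"agnosia_sp04","agnosia"
"agnosia_sp05","agnosia"
"agnosia_sp06","agnosia"
"agnosia_sp07","agnosia"
"confusa_sp01","confusa"
"confusa_sp02","confusa"
"confusa_sp03","confusa"
"confusa_sp04","confusa"
"confusa_sp05","confusa"
"confusa_sp06","confusa"
"theudelinda_sp01","theudelinda"
"theudelinda_sp02","theudelinda"
"theudelinda_sp03","theudelinda"
"theudelinda_sp04","theudelinda"
"theudelinda_sp05","theudelinda"
"aureliana_sp01","aureliana"
"aureliana_sp02","aureliana"
"aureliana_sp03","aureliana"
"aureliana_sp04","aureliana"
"banjana_m_sp01","banjana-m"
"banjana_m_sp02","banjana-m"
"banjana_m_sp03","banjana-m"
"banjana_m_sp04","banjana-m"
"hewitsoni_sp01","hewitsoni"
"hewitsoni_sp02","hewitsoni"
"hewitsoni_sp03","hewitsoni"
"blue_sp01","blue"
"blue_sp02","blue"
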