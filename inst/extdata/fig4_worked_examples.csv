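structure_id,compound_id,form,E_inter,E_intra_global,E_latt_global,provenance
ACBNZA02,ACBNZA,alpha,-146.9,15,-131.9,E_inter and E_intra-global printed for the metastable alpha form (adjustment-dominated); E_latt-global is their sum (printed as approximately -132)
ACBNZA01,ACBNZA,beta,-205.3,70.9,-134.4,E_inter printed; E_latt-global derived as E_latt(alpha) - dE_latt(2.5) = -134.4; E_intra-global = E_latt - E_inter = 70.9 (printed as approximately 71)
YIGPIO02,YIGPIO,I,-393,102,-291,E_latt-global (-291) and E_intra-global (102) printed for form I; E_inter derived as E_latt - E_intra = -393
YIGPIO03,YIGPIO,II,-426,129,-297,E_latt-global (-297) and E_intra-global (129) printed for form II; E_inter derived as E_latt - E_intra = -426 (not printed directly)
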