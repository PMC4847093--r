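# cspascore bundled chemical profiles: scores for the 21 most frequently
# reported CSPA chemicals/groups. NI = no information (missing); NA = not
# applicable (potency without a certainty classification).
chemical_id,name,group,abs_oral_score,abs_dermal_score,abs_inhalation_score,solubility_score,kp_score,vp_score,rd_certainty,rd_potency,carc_certainty,carc_potency,nt_certainty,nt_potency,ed_certainty,ed_potency
dibutyl_phthalate,Dibutyl phthalate,phthalates,3,2,2,1,3,1,3,3,0,NA,3,2,3,3
di_2_ethylhexyl_phthalate,Di-2-ethylhexyl phthalate,phthalates,3,2,2,1,2,1,3,3,3,1,0,NA,3,3
formaldehyde,Formaldehyde,none,2,3,3,3,1,3,1,1,3,3,3,2,0,NA
butyl_benzyl_phthalate,Butyl benzyl phthalate,phthalates,3,2,3,1,3,1,3,3,0,NA,0,NA,3,3
styrene,Styrene,none,2,2,3,1,3,2,2,1,3,3,3,2,0,NA
diisodecyl_phthalate,Diisodecyl phthalate,phthalates,3,NI,3,1,2,1,3,3,0,NA,0,NA,2,1
methyl_ethyl_ketone,Methyl Ethyl Ketone,none,2,NI,3,3,2,3,3,1,0,NA,3,2,0,NA
di_n_hexyl_phthalate,Di-n-Hexyl phthalate,phthalates,NI,3,NI,1,2,1,3,3,0,NA,0,NA,2,1
butyl_paraben,Butyl Paraben,parabens,NI,NI,NI,1,3,1,0,NA,0,NA,0,NA,3,3
ethylene_glycol,Ethylene Glycol,ethylene_glycols,2,1,3,3,1,2,2,1,0,NA,3,2,0,NA
ethyl_paraben,Ethyl Paraben,parabens,NI,NI,NI,1,3,1,0,NA,0,NA,0,NA,3,1
cobalt,Cobalt and Cobalt Compounds,metals,3,1,3,1,1,1,1,1,3,3,0,NA,0,NA
diethyl_phthalate,Diethyl phthalate,phthalates,2,1,NI,1,2,1,0,NA,1,1,0,NA,3,3
antimony,Antimony and Antimony Compounds,metals,2,2,2,1,NI,1,0,NA,3,1,0,NA,0,NA
diisononyl_phthalate,Diisononyl phthalate,phthalates,3,1,3,1,2,1,1,1,0,NA,0,NA,2,1
di_n_octyl_phthalate,Di-n-octyl phthalate,phthalates,2,NI,NI,1,2,1,1,1,0,NA,0,NA,1,1
octamethylcyclotetrasiloxane,Octamethylcyclotetrasiloxane,none,NI,NI,NI,1,3,3,1,1,0,NA,0,NA,0,NA
methyl_paraben,Methyl Paraben,parabens,NI,NI,NI,2,2,1,0,NA,0,NA,0,NA,0,NA
molybdenum,Molybdenum and Molybdenum Compounds,metals,NI,NI,NI,1,1,1,0,NA,0,NA,0,NA,0,NA
phthalic_anhydride,Phthalic anhydride,phthalates,NI,NI,NI,2,1,1,0,NA,0,NA,0,NA,0,NA
propyl_paraben,Propyl paraben,parabens,NI,NI,NI,1,3,1,0,NA,0,NA,0,NA,0,NA
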