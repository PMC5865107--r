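pollinator_species,site,n_hoverflies,dprime
Cheilosia illustrata,CAD,0,
Cheilosia illustrata,LLC,6,0.23
Cheilosia illustrata,TRE,3,0.17
Eristalis arbustorum,CAD,0,
Eristalis arbustorum,LLC,2,0.09
Eristalis arbustorum,TRE,0,
Eristalis horticola,CAD,9,0.08
Eristalis horticola,LLC,11,0.04
Eristalis horticola,TRE,1,0.19
Eristalis intricaria,CAD,1,0.00
Eristalis intricaria,LLC,0,
Eristalis intricaria,TRE,0,
Eristalis nemorum,CAD,3,0.09
Eristalis nemorum,LLC,3,0.03
Eristalis nemorum,TRE,8,0.14
Eristalis pertinax,CAD,25,0.12
Eristalis pertinax,LLC,6,0.04
Eristalis pertinax,TRE,4,0.09
Eristalis tenax,CAD,3,0.10
Eristalis tenax,LLC,10,0.06
Eristalis tenax,TRE,2,0.17
Rhingia campestris,CAD,8,0.19
Rhingia campestris,LLC,1,0.37
Rhingia campestris,TRE,2,0.15
Sericomyia silentis,CAD,14,0.21
Sericomyia silentis,LLC,5,0.19
Sericomyia silentis,TRE,5,0.24
Sericomyia superbiens,CAD,5,0.32
Sericomyia superbiens,LLC,0,
Sericomyia superbiens,TRE,2,0.12
Volucella bombylans,CAD,1,0.15
Volucella bombylans,LLC,0,
Volucella bombylans,TRE,3,0.20
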