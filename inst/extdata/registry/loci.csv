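locus,copy_number,unit_length_bp,motif_class,rm_flag,canonical_spacer_bp,excluded_single_units,modal_allele
DYS19,1,4,complex,FALSE,NA,,15
DYS388,1,3,simple,FALSE,NA,,12
DYS389I,1,4,compound,FALSE,NA,,13
DYS389II,1,4,complex,FALSE,48,,29
DYS390,1,4,compound,FALSE,NA,,23
DYS391,1,4,simple,FALSE,NA,,10
DYS392,1,3,compound,FALSE,NA,,13
DYS393,1,4,simple,FALSE,NA,,13
DYS437,1,4,compound,FALSE,NA,,14
DYS438,1,5,simple,FALSE,NA,,10
DYS439,1,4,simple,FALSE,NA,,12
DYS444,1,4,simple,FALSE,NA,,12
DYS447,1,5,simple,FALSE,NA,,24
DYS448,1,6,complex,FALSE,42,,19
DYS449,1,4,complex,TRUE,NA,,30
DYS456,1,4,simple,FALSE,NA,,15
DYS458,1,4,simple,FALSE,NA,,17
DYS460,1,4,simple,FALSE,NA,GTAT,10
DYS481,1,3,simple,FALSE,NA,,23
DYS518,1,4,complex,TRUE,NA,,38
DYS522,1,4,simple,FALSE,NA,,11
DYS549,1,4,simple,FALSE,NA,,12
DYS533,1,4,simple,FALSE,NA,,11
DYS557,1,4,simple,FALSE,NA,,15
DYS570,1,4,simple,TRUE,NA,,17
DYS576,1,4,simple,TRUE,NA,,18
DYS593,1,5,simple,FALSE,NA,,15
DYS596,1,6,simple,FALSE,NA,,11
DYS627,1,4,compound,TRUE,NA,,21
DYS635,1,4,complex,FALSE,NA,,21
DYS643,1,5,simple,FALSE,NA,,10
DYS645,1,5,simple,FALSE,NA,,8
Y-GATA-H4,1,4,simple,FALSE,NA,,12
DYF387S1a/b,2,4,complex,TRUE,NA,,37
DYF404S1a/b,2,4,simple,TRUE,NA,,13
DYS385a/b,2,4,simple,FALSE,NA,,13
DYS527a/b,2,4,complex,FALSE,NA,,21
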