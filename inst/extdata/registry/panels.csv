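panel,locus
MH,DYS19
MH,DYS389I
MH,DYS389II
MH,DYS390
MH,DYS391
MH,DYS392
MH,DYS393
MH,DYS385a/b
SWGDAM,DYS19
SWGDAM,DYS389I
SWGDAM,DYS389II
SWGDAM,DYS390
SWGDAM,DYS391
SWGDAM,DYS392
SWGDAM,DYS393
SWGDAM,DYS438
SWGDAM,DYS439
SWGDAM,DYS385a/b
Yfiler,DYS19
Yfiler,DYS389I
Yfiler,DYS389II
Yfiler,DYS390
Yfiler,DYS391
Yfiler,DYS392
Yfiler,DYS393
Yfiler,DYS437
Yfiler,DYS438
Yfiler,DYS439
Yfiler,DYS448
Yfiler,DYS456
Yfiler,DYS458
Yfiler,DYS635
Yfiler,Y-GATA-H4
Yfiler,DYS385a/b
PPY23,DYS19
PPY23,DYS389I
PPY23,DYS389II
PPY23,DYS390
PPY23,DYS391
PPY23,DYS392
PPY23,DYS393
PPY23,DYS437
PPY23,DYS438
PPY23,DYS439
PPY23,DYS448
PPY23,DYS456
PPY23,DYS458
PPY23,DYS481
PPY23,DYS533
PPY23,DYS549
PPY23,DYS570
PPY23,DYS576
PPY23,DYS635
PPY23,DYS643
PPY23,Y-GATA-H4
PPY23,DYS385a/b
YfilerPlus,DYS19
YfilerPlus,DYS389I
YfilerPlus,DYS389II
YfilerPlus,DYS390
YfilerPlus,DYS391
YfilerPlus,DYS392
YfilerPlus,DYS393
YfilerPlus,DYS437
YfilerPlus,DYS438
YfilerPlus,DYS439
YfilerPlus,DYS448
YfilerPlus,DYS449
YfilerPlus,DYS456
YfilerPlus,DYS458
YfilerPlus,DYS460
YfilerPlus,DYS481
YfilerPlus,DYS518
YfilerPlus,DYS533
YfilerPlus,DYS570
YfilerPlus,DYS576
YfilerPlus,DYS627
YfilerPlus,DYS635
YfilerPlus,Y-GATA-H4
YfilerPlus,DYF387S1a/b
YfilerPlus,DYS385a/b
Ymax,DYS19
Ymax,DYS389I
Ymax,DYS389II
Ymax,DYS390
Ymax,DYS391
Ymax,DYS392
Ymax,DYS393
Ymax,DYS437
Ymax,DYS438
Ymax,DYS439
Ymax,DYS448
Ymax,DYS449
Ymax,DYS456
Ymax,DYS458
Ymax,DYS460
Ymax,DYS481
Ymax,DYS518
Ymax,DYS533
Ymax,DYS570
Ymax,DYS576
Ymax,DYS627
Ymax,DYS635
Ymax,Y-GATA-H4
Ymax,DYF387S1a/b
Ymax,DYF404S1a/b
Ymax,DYS385a/b
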