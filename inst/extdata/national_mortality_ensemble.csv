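"system","study","population","deaths"
"Illinois-1","Bell et al. 2004","ICLUS-A1",570
"Illinois-1","Bell et al. 2004","ICLUS-A2",520
"Illinois-1","Bell et al. 2004","ICLUS-BC",510
"Illinois-1","Bell et al. 2004","W&P",440
"Illinois-1","Bell et al. 2004","Census 2000",170
"Illinois-1","Ito et al. 2005","ICLUS-A1",2560
"Illinois-1","Ito et al. 2005","ICLUS-A2",2340
"Illinois-1","Ito et al. 2005","ICLUS-BC",2280
"Illinois-1","Ito et al. 2005","W&P",1970
"Illinois-1","Ito et al. 2005","Census 2000",780
"Illinois-1","Schwartz 2005","ICLUS-A1",860
"Illinois-1","Schwartz 2005","ICLUS-A2",790
"Illinois-1","Schwartz 2005","ICLUS-BC",770
"Illinois-1","Schwartz 2005","W&P",670
"Illinois-1","Schwartz 2005","Census 2000",270
"Illinois-2","Bell et al. 2004","ICLUS-A1",530
"Illinois-2","Bell et al. 2004","ICLUS-A2",480
"Illinois-2","Bell et al. 2004","ICLUS-BC",480
"Illinois-2","Bell et al. 2004","W&P",420
"Illinois-2","Bell et al. 2004","Census 2000",160
"Illinois-2","Ito et al. 2005","ICLUS-A1",2390
"Illinois-2","Ito et al. 2005","ICLUS-A2",2180
"Illinois-2","Ito et al. 2005","ICLUS-BC",2160
"Illinois-2","Ito et al. 2005","W&P",1870
"Illinois-2","Ito et al. 2005","Census 2000",710
"Illinois-2","Schwartz 2005","ICLUS-A1",810
"Illinois-2","Schwartz 2005","ICLUS-A2",730
"Illinois-2","Schwartz 2005","ICLUS-BC",730
"Illinois-2","Schwartz 2005","W&P",640
"Illinois-2","Schwartz 2005","Census 2000",250
"CMU","Bell et al. 2004","ICLUS-A1",480
"CMU","Bell et al. 2004","ICLUS-A2",430
"CMU","Bell et al. 2004","ICLUS-BC",430
"CMU","Bell et al. 2004","W&P",350
"CMU","Bell et al. 2004","Census 2000",150
"CMU","Ito et al. 2005","ICLUS-A1",2180
"CMU","Ito et al. 2005","ICLUS-A2",1950
"CMU","Ito et al. 2005","ICLUS-BC",1920
"CMU","Ito et al. 2005","W&P",1570
"CMU","Ito et al. 2005","Census 2000",690
"CMU","Schwartz 2005","ICLUS-A1",730
"CMU","Schwartz 2005","ICLUS-A2",660
"CMU","Schwartz 2005","ICLUS-BC",650
"CMU","Schwartz 2005","W&P",540
"CMU","Schwartz 2005","Census 2000",240
"Harvard","Bell et al. 2004","ICLUS-A1",240
"Harvard","Bell et al. 2004","ICLUS-A2",220
"Harvard","Bell et al. 2004","ICLUS-BC",230
"Harvard","Bell et al. 2004","W&P",200
"Harvard","Bell et al. 2004","Census 2000",80
"Harvard","Ito et al. 2005","ICLUS-A1",1090
"Harvard","Ito et al. 2005","ICLUS-A2",1000
"Harvard","Ito et al. 2005","ICLUS-BC",1030
"Harvard","Ito et al. 2005","W&P",890
"Harvard","Ito et al. 2005","Census 2000",380
"Harvard","Schwartz 2005","ICLUS-A1",370
"Harvard","Schwartz 2005","ICLUS-A2",340
"Harvard","Schwartz 2005","ICLUS-BC",350
"Harvard","Schwartz 2005","W&P",300
"Harvard","Schwartz 2005","Census 2000",130
"GNM","Bell et al. 2004","ICLUS-A1",40
"GNM","Bell et al. 2004","ICLUS-A2",30
"GNM","Bell et al. 2004","ICLUS-BC",20
"GNM","Bell et al. 2004","W&P",10
"GNM","Bell et al. 2004","Census 2000",-20
"GNM","Ito et al. 2005","ICLUS-A1",180
"GNM","Ito et al. 2005","ICLUS-A2",140
"GNM","Ito et al. 2005","ICLUS-BC",80
"GNM","Ito et al. 2005","W&P",50
"GNM","Ito et al. 2005","Census 2000",-80
"GNM","Schwartz 2005","ICLUS-A1",60
"GNM","Schwartz 2005","ICLUS-A2",50
"GNM","Schwartz 2005","ICLUS-BC",30
"GNM","Schwartz 2005","W&P",20
"GNM","Schwartz 2005","Census 2000",-30
"NERL","Bell et al. 2004","ICLUS-A1",10
"NERL","Bell et al. 2004","ICLUS-A2",10
"NERL","Bell et al. 2004","ICLUS-BC",-10
"NERL","Bell et al. 2004","W&P",-50
"NERL","Bell et al. 2004","Census 2000",-20
"NERL","Ito et al. 2005","ICLUS-A1",50
"NERL","Ito et al. 2005","ICLUS-A2",20
"NERL","Ito et al. 2005","ICLUS-BC",-40
"NERL","Ito et al. 2005","W&P",-240
"NERL","Ito et al. 2005","Census 2000",-100
"NERL","Schwartz 2005","ICLUS-A1",20
"NERL","Schwartz 2005","ICLUS-A2",10
"NERL","Schwartz 2005","ICLUS-BC",-20
"NERL","Schwartz 2005","W&P",-80
"NERL","Schwartz 2005","Census 2000",-40
"WSU","Bell et al. 2004","ICLUS-A1",-150
"WSU","Bell et al. 2004","ICLUS-A2",-140
"WSU","Bell et al. 2004","ICLUS-BC",-110
"WSU","Bell et al. 2004","W&P",-60
"WSU","Bell et al. 2004","Census 2000",0
"WSU","Ito et al. 2005","ICLUS-A1",-650
"WSU","Ito et al. 2005","ICLUS-A2",-630
"WSU","Ito et al. 2005","ICLUS-BC",-480
"WSU","Ito et al. 2005","W&P",-240
"WSU","Ito et al. 2005","Census 2000",0
"WSU","Schwartz 2005","ICLUS-A1",-220
"WSU","Schwartz 2005","ICLUS-A2",-210
"WSU","Schwartz 2005","ICLUS-BC",-160
"WSU","Schwartz 2005","W&P",-90
"WSU","Schwartz 2005","Census 2000",0
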