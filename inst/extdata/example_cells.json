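{"cells":[{"cell_id":"syn001_prophase","lineage":"a6.5","stage":32,"phase":"prophase","group":"control","contour_um":[[-4.93083619526533,7.54439989484453],[-5.93449646774336,6.74759289360336],[-6.53820380677449,5.4195162217167],[-6.72172665771407,3.67513554554674],[-6.41585087814975,1.5986357225413],[-5.5610966059125,-0.641590391134201],[-4.26424042564989,-2.78700378150374],[-2.72902896426417,-4.68031688076074],[-1.07106920936296,-6.28368833117576],[0.655129241358004,-7.48342669897941],[2.31896599767132,-8.09218534693549],[3.76696495758872,-8.07690788398574],[4.95013247212738,-7.57392406140854],[5.85394431485525,-6.65600414005929],[6.38477046387035,-5.29233534522587],[6.47126849920863,-3.5381963738327],[6.17526335159608,-1.53868859757672],[5.5439401421813,0.639611029318385],[4.47399718894943,2.9240956980372],[2.91523086017681,4.99965532974073],[1.10109925513006,6.45986690723954],[-0.633724123014139,7.23891977729593],[-2.18402821414218,7.62131101944685],[-3.62640519672046,7.77552779324694]],"poles_um":[[-0.0157664766134293,-3.25818632883496],[-3.15603927243516,3.18024174887679]]},{"cell_id":"syn001_metaphase","lineage":"a6.5","stage":32,"phase":"metaphase","group":"control","contour_um":[[-4.93083619526533,7.54439989484453],[-5.93449646774336,6.74759289360336],[-6.53820380677449,5.4195162217167],[-6.72172665771407,3.67513554554674],[-6.41585087814975,1.5986357225413],[-5.5610966059125,-0.641590391134201],[-4.26424042564989,-2.78700378150374],[-2.72902896426417,-4.68031688076074],[-1.07106920936296,-6.28368833117576],[0.655129241358004,-7.48342669897941],[2.31896599767132,-8.09218534693549],[3.76696495758872,-8.07690788398574],[4.95013247212738,-7.57392406140854],[5.85394431485525,-6.65600414005929],[6.38477046387035,-5.29233534522587],[6.47126849920863,-3.5381963738327],[6.17526335159608,-1.53868859757672],[5.5439401421813,0.639611029318385],[4.47399718894943,2.9240956980372],[2.91523086017681,4.99965532974073],[1.10109925513006,6.45986690723954],[-0.633724123014139,7.23891977729593],[-2.18402821414218,7.62131101944685],[-3.62640519672046,7.77552779324694]],"poles_um":[[1.23911003307027,-4.17062457453568],[-1.90116276275146,2.26780350317608]]},{"cell_id":"syn002_prophase","lineage":"a6.6","stage":32,"phase":"prophase","group":"control","contour_um":[[-3.87595121583785,8.44915414164907],[-5.14890176164509,7.90156955754263],[-6.07587175348759,6.65717015319898],[-6.41301086849599,4.72142812953452],[-6.20214626362873,2.44667340131924],[-5.6555020281653,0.114512621221689],[-4.83932904589479,-2.21998592815522],[-3.67473070379735,-4.44916704952375],[-2.19296023285467,-6.30232748301612],[-0.579453579641888,-7.61223470911414],[1.02127558679486,-8.44013835083797],[2.56662206761605,-8.83667495465256],[3.9852167753959,-8.68734123526034],[5.1382683559903,-7.88525139916549],[5.92011817699664,-6.48651512578265],[6.28942573961659,-4.63044149067667],[6.21949028340421,-2.45351541214145],[5.71474850162417,-0.115712243985532],[4.84255620980301,2.2214663520727],[3.66787747358874,4.44086952557309],[2.21873445001595,6.37639975972006],[0.590545985055022,7.75795473995007],[-1.02113297070694,8.43895972723369],[-2.49588918174525,8.59314727329612]],"poles_um":[[1.90219191424276,-4.40331016272735],[-0.475925576980835,2.77132003216024]]},{"cell_id":"syn002_metaphase","lineage":"a6.6","stage":32,"phase":"metaphase","group":"control","contour_um":[[-3.87595121583785,8.44915414164907],[-5.14890176164509,7.90156955754263],[-6.07587175348759,6.65717015319898],[-6.41301086849599,4.72142812953452],[-6.20214626362873,2.44667340131924],[-5.6555020281653,0.114512621221689],[-4.83932904589479,-2.21998592815522],[-3.67473070379735,-4.44916704952375],[-2.19296023285467,-6.30232748301612],[-0.579453579641888,-7.61223470911414],[1.02127558679486,-8.44013835083797],[2.56662206761605,-8.83667495465256],[3.9852167753959,-8.68734123526034],[5.1382683559903,-7.88525139916549],[5.92011817699664,-6.48651512578265],[6.28942573961659,-4.63044149067667],[6.21949028340421,-2.45351541214145],[5.71474850162417,-0.115712243985532],[4.84255620980301,2.2214663520727],[3.66787747358874,4.44086952557309],[2.21873445001595,6.37639975972006],[0.590545985055022,7.75795473995007],[-1.02113297070694,8.43895972723369],[-2.49588918174525,8.59314727329612]],"poles_um":[[0.827797071955725,-3.48816459308705],[-1.55032041926787,3.68646560180054]]},{"cell_id":"syn003_prophase","lineage":"a6.7","stage":32,"phase":"prophase","group":"control","contour_um":[[-8.31963123942286,7.17877356865667],[-8.87727919592502,5.84667538547127],[-8.66737639916455,4.06267177979852],[-7.94902531095729,2.1101315363016],[-6.90888005357221,0.0838955192866471],[-5.46507896746072,-2.02639394458183],[-3.51928485770352,-4.07857302679306],[-1.22461270750497,-5.79906094085711],[1.12757914131602,-7.02733103917581],[3.3430083915471,-7.76730945741657],[5.31379621512851,-8.0179256902214],[6.90288416813307,-7.72333256088466],[7.99336833051965,-6.89725056848222],[8.57780716401174,-5.64943975516372],[8.677923430524,-4.0676155049457],[8.23568326777232,-2.18622715446165],[7.17889165600568,-0.0871743088189518],[5.54583635185573,2.05633793545418],[3.48671873244221,4.04083146126243],[1.20067022701823,5.68568313368016],[-1.10271165091096,6.87235115280977],[-3.2708373141976,7.5996236409328],[-5.26039330516196,7.93734665662309],[-7.01905607429258,7.85331218152553]],"poles_um":[[2.62380885162861,-1.10978786121115],[-4.50619928636515,3.46794319355522]]},{"cell_id":"syn003_metaphase","lineage":"a6.7","stage":32,"phase":"metaphase","group":"control","contour_um":[[-8.31963123942286,7.17877356865667],[-8.87727919592502,5.84667538547127],[-8.66737639916455,4.06267177979852],[-7.94902531095729,2.1101315363016],[-6.90888005357221,0.0838955192866471],[-5.46507896746072,-2.02639394458183],[-3.51928485770352,-4.07857302679306],[-1.22461270750497,-5.79906094085711],[1.12757914131602,-7.02733103917581],[3.3430083915471,-7.76730945741657],[5.31379621512851,-8.0179256902214],[6.90288416813307,-7.72333256088466],[7.99336833051965,-6.89725056848222],[8.57780716401174,-5.64943975516372],[8.677923430524,-4.0676155049457],[8.23568326777232,-2.18622715446165],[7.17889165600568,-0.0871743088189518],[5.54583635185573,2.05633793545418],[3.48671873244221,4.04083146126243],[1.20067022701823,5.68568313368016],[-1.10271165091096,6.87235115280977],[-3.2708373141976,7.5996236409328],[-5.26039330516196,7.93734665662309],[-7.01905607429258,7.85331218152553]],"poles_um":[[2.98275982807332,-0.829849852936296],[-4.14724830992044,3.74788120183007]]}]}
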