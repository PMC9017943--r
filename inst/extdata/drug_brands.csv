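brand,inn
Herceptin,trastuzumab
Kadcyla,trastuzumab emtansine
Perjeta,pertuzumab
Avastin,bevacizumab
Tecentriq,atezolizumab
Taxol,paclitaxel
Taxotere,docetaxel
Paraplatin,carboplatin
Cisplatyl,cisplatin
Alimta,pemetrexed
Navelbine,vinorelbine
Gemzar,gemcitabine
Xeloda,capecitabine
Endoxan,cyclophosphamide
Farmorubicine,epirubicin
Adriblastine,doxorubicin
Mabthera,rituximab
Velcade,bortezomib
Darzalex,daratumumab
Revlimid,lenalidomide
Glivec,imatinib
Vidaza,azacitidine
Eloxatine,oxaliplatin
Campto,irinotecan
Erbitux,cetuximab
Vectibix,panitumumab
Temodal,temozolomide
Yervoy,ipilimumab
Aracytine,cytarabine
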