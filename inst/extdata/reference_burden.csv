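section,key,direct_2004,indirect_2004,total_2004,direct_2015,indirect_2015,total_2015,delta_total
disease,Colorectal cancer,109029668,538606562,647636230,107214127,529637786,636851914,-10784316
disease,Esophagus cancer,46535728,229886495,276422223,46066272,227567383,273633657,-2788566
disease,Stomach cancer,29279371,144640095,173919467,28986576,143193684,172180259,-1739208
disease,Hepatocellular cancer,13984178,69081841,83066020,13690859,67632841,81323699,-1742321
disease,Larynx cancer,34245916,169174824,203420740,33972017,167821764,201793781,-1626959
disease,Oral cancer,130646735,645394871,776041605,133179854,657908477,791088329,15046724
disease,Pancreas cancer,73198999,361603055,434802054,72929263,360270561,433199823,-1602231
disease,Prostate cancer,58109777,287062299,345172076,57213470,282634542,339848013,-5324063
disease,Lung cancer,139890329,691058228,830948557,138337103,683385288,821722390,-9226167
disease,Type 2 diabetes,736615873,891305206,1627921078,700673101,847814453,1548487553,-79433525
disease,Ischemic stroke,418337971,719541310,1137879280,426446233,733487522,1159933756,22054476
disease,Heart failure,466812796,802918010,1269730807,474620236,816346806,1290967042,21236235
disease,Ischemic heart disease,1989777241,3422416855,5412194096,1961447510,3373689716,5335137226,-77056870
age,<15,15660895,28136790,43797685,13472001,24535613,38007614,-5790071
age,15-34,63552723,103521887,167074610,57540350,94324290,151864640,-15209970
age,35-54,736993367,1398889539,2135882906,674024835,1284894880,1958919714,-176963192
age,55-64,923070850,1945257212,2868328061,878618081,1854232431,2732850513,-135477549
age,65-74,1080673531,2340889315,3421562847,1090851811,2366372315,3457224126,35661280
age,75+,1426513218,3155994905,4582508123,1480269544,3267031295,4747300839,164792716
sex,male,2687141216,5719965722,8407106937,2609869447,5578584181,8188453627,-218653311
sex,female,1559323367,3252723929,4812047295,1584907173,3312806643,4897713815,85666521
total,total,4246464583,8972689651,13219154232,4194776620,8891390823,13086167443,-132986787
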