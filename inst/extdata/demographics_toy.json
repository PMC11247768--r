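{"reference_year":2020,"states":[{"state_code":"AA","zip_codes":["81654","62411","85424","94558","67453","64199"],"pop_by_age":{"0":1569,"1":1569,"2":1569,"3":1569,"4":1569,"5":1703,"6":1703,"7":1703,"8":1703,"9":1703,"10":1703,"11":1703,"12":1703,"13":1703,"14":1703,"15":1743,"16":1743,"17":1744,"18":1743,"19":1743,"20":1737,"21":1737,"22":1737,"23":1737,"24":1737,"25":1832,"26":1832,"27":1832,"28":1832,"29":1832,"30":1832,"31":1832,"32":1832,"33":1832,"34":1832,"35":1831,"36":1832,"37":1832,"38":1832,"39":1832,"40":1700,"41":1700,"42":1699,"43":1700,"44":1700,"45":1700,"46":1699,"47":1700,"48":1700,"49":1699,"50":1700,"51":1700,"52":1700,"53":1699,"54":1700,"55":1700,"56":1700,"57":1699,"58":1700,"59":1700,"60":1699,"61":1146,"62":1145,"63":1145,"64":1146,"65":1145,"66":1145,"67":1146,"68":1145,"69":1145,"70":1146,"71":1145,"72":1146,"73":1145,"74":1145,"75":1146,"76":1145,"77":1145,"78":1146,"79":1145,"80":1145,"81":1146,"82":1145,"83":1145,"84":1146,"85+":1145},"sex_percent":{"male":48.4122758137994,"female":51.5877241862006},"race_percent":{"African-American":18.7534230417075,"European-American":51.9633413342908,"Others":29.2832356240017}},{"state_code":"AB","zip_codes":["88929","84637","15651","88657","93151","27688","10581"],"pop_by_age":{"0":1957,"1":1958,"2":1957,"3":1957,"4":1958,"5":2124,"6":2125,"7":2124,"8":2125,"9":2124,"10":2125,"11":2124,"12":2124,"13":2125,"14":2124,"15":2175,"16":2175,"17":2175,"18":2175,"19":2174,"20":2167,"21":2167,"22":2167,"23":2167,"24":2167,"25":2285,"26":2285,"27":2286,"28":2285,"29":2285,"30":2286,"31":2285,"32":2285,"33":2286,"34":2285,"35":2286,"36":2285,"37":2285,"38":2286,"39":2285,"40":2120,"41":2121,"42":2120,"43":2121,"44":2120,"45":2120,"46":2121,"47":2120,"48":2121,"49":2120,"50":2120,"51":2121,"52":2120,"53":2121,"54":2120,"55":2120,"56":2121,"57":2120,"58":2121,"59":2120,"60":2120,"61":1429,"62":1429,"63":1429,"64":1429,"65":1429,"66":1428,"67":1429,"68":1429,"69":1429,"70":1429,"71":1429,"72":1428,"73":1429,"74":1429,"75":1429,"76":1429,"77":1428,"78":1429,"79":1429,"80":1429,"81":1429,"82":1429,"83":1428,"84":1429,"85+":1429},"sex_percent":{"male":48.6416213743389,"female":51.3583786256611},"race_percent":{"African-American":14.6751193612805,"European-American":60.735512904361,"Others":24.5893677343584}},{"state_code":"AC","zip_codes":["13400","67811","96343","76839","78525","19318","09385","87178"],"pop_by_age":{"0":3495,"1":3494,"2":3495,"3":3495,"4":3494,"5":3794,"6":3793,"7":3793,"8":3793,"9":3793,"10":3793,"11":3793,"12":3793,"13":3793,"14":3794,"15":3883,"16":3882,"17":3883,"18":3883,"19":3883,"20":3869,"21":3869,"22":3869,"23":3868,"24":3869,"25":4081,"26":4080,"27":4080,"28":4081,"29":4080,"30":4080,"31":4081,"32":4080,"33":4080,"34":4081,"35":4080,"36":4080,"37":4081,"38":4080,"39":4080,"40":3786,"41":3786,"42":3786,"43":3786,"44":3786,"45":3786,"46":3785,"47":3786,"48":3786,"49":3786,"50":3786,"51":3786,"52":3786,"53":3785,"54":3786,"55":3786,"56":3786,"57":3786,"58":3786,"59":3785,"60":3786,"61":2551,"62":2551,"63":2552,"64":2551,"65":2551,"66":2551,"67":2551,"68":2551,"69":2551,"70":2551,"71":2551,"72":2551,"73":2551,"74":2551,"75":2551,"76":2551,"77":2551,"78":2552,"79":2551,"80":2551,"81":2551,"82":2551,"83":2551,"84":2551,"85+":2551},"sex_percent":{"male":49.6583718003705,"female":50.3416281996295},"race_percent":{"African-American":19.6519322526012,"European-American":56.8235385784853,"Others":23.5245291689135}}]}
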