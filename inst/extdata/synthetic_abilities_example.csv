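participant_id,age,km_per_year,licence_years,vmc_time_close,moa_mean_time,mot_speed,nback_acc_diff,nback_rt_diff,corsi_span,ssrt,flanker_acc,flanker_rt_diff,tmt_b_minus_a,tol_correct,tol_extra_moves,success
S0001,0.2759319911460378,0.9477858149541607,1.4376265724357689,-0.6248028084508128,1.9377753689260429,1.268810392906757,-0.4151290565719788,2.1831165656965448,0.7772256630733576,0.468267985537406,0.12222932036517226,1.379529422188792,1.2683586499075679,0.21729681444349563,1.2362391180120826,1
S0002,1.2237896765515284,-0.10139311215926794,-1.2404621079747706,-0.9213862025737647,1.4238854572594304,-1.2959817044222794,-0.7126688690822611,-0.17619118873670409,0.4797113877521994,-0.384088673556006,-1.345710964692398,-0.6726001963469634,0.7600746323794441,-1.4829967225135638,-2.3617431247442764,1
S0003,1.6104730293219605,-0.9841200030566506,0.45885642117108383,-0.90129429537087,0.2692900426592842,0.3618939734834212,-0.28841133819238085,-0.6515057786498691,1.0153329158553805,1.1317926749363851,0.07930191963491973,1.1220555964839043,-1.7368786519968276,0.5870218964326794,-1.8078634660583308,1
S0004,0.01410640905706495,-0.22233183898572262,-0.9118898629705882,0.2925237706197497,0.7643518479330204,0.6560441782832054,-0.6521057155285105,1.4298865596804202,1.895534520130813,0.6179911595812653,1.475194830676768,-0.6198262630829523,-2.1275586581319854,0.39696522817342433,-1.19269576418286,0
S0005,0.27906875575557266,-1.1304934640664597,1.6020723393875236,0.7897315129786883,-1.8533537806938276,-0.08602569898061038,0.4852451159334853,-0.7095713791139648,-0.2351121059243662,-0.3021656788463823,0.4941614203067515,0.8533259918895472,-1.522117927431247,0.1257337876745217,0.6606880643281324,0
S0006,0.41822026450590655,-0.7232758201896542,-0.5101325730543362,-1.5669360406275894,-0.7058788765014374,-2.5204194854064474,-1.5555005657670207,-2.544212012544841,-3.392803594315825,-1.1442049423114036,-1.7780985922530528,-0.6431927003806651,-2.3533620648691462,-0.8019586811627291,-0.3248330261652448,1
S0007,-0.8018900366231542,-0.9055000684036645,-0.6358855151654725,-0.5325044906472054,-0.8154681173382734,-0.3070091347788542,-0.2676267545272071,-1.2633686337026926,-0.8129516209681646,-0.20488792653155036,-0.014032413851628345,-0.30592347671546977,0.3307727270175864,0.7603617184604847,-1.082440882662803,0
S0008,-0.30738699307277917,-0.6632032915274593,0.24606438075644332,-1.4505015365660747,-0.6041634620887165,-0.1569057328976271,-0.33365375516785545,-0.41895637377315054,-1.1502339982942786,-1.4133632943374783,-0.677432021252415,0.5848537770199516,-0.049508145883167654,-1.0582666570110648,-0.4148028091810869,1
S0009,-0.17704860148001617,-1.0550580775416767,-0.9827968122422318,0.9414832828429756,0.544655877503638,0.935739190689153,-1.611750015074931,-0.3356330492673694,-0.21392748341983875,1.156350612445218,-0.09553789254126387,-0.2780313609392916,1.6398951797539096,-0.4848430608042624,0.6083405121803873,1
S0010,0.08576382246220951,-1.0713903165702623,1.1377300406537127,0.2906292682473427,0.7123528700356998,0.2356633387471109,0.09783341252690783,0.1982906235387675,0.8179334650870781,-0.6947065952117633,0.5683772369020107,-0.5368933918481282,-0.03748535653980645,0.4462991828626589,0.2219936633824572,0
S0011,-0.019386297339282516,-0.06274502502186065,-1.2160663504930926,-1.5816924409088176,-0.22386274430919734,0.3334429159021596,1.1605429538226846,-0.3876978183042072,-0.69138794301306306,-0.44751436169169745,0.3594084489002445,-0.1885995587219853,-0.49079006526633473,0.35565314051902785,0.2932264354496791,0
S0012,0.7149846232447732,-1.2202396134589064,-1.7191145071113314,0.998055865060218,2.0334718766833157,0.6953941549591116,-0.33894744116851705,-1.9875771859336036,-1.0473769054473654,0.28890191828066686,0.5026897026130905,-0.4165250277249162,1.1157621399739923,0.6651634099442647,-0.15007947899720106,0
S0013,0.4318066855593402,-0.22556469038859875,-0.1484447043619979,-1.144798335913239,0.4277932999664148,-0.7317900192290924,-0.7924298421416839,-0.35812191464047516,0.34155988635509815,-0.4559124396574863,0.3106579410313607,-0.23193425304909437,0.5947860893325115,-0.10921751871398365,0.19306075390529723,1
S0014,-0.8986202580077325,0.048676192300010176,0.6585532353193484,-1.0419377330230923,-0.2820000103898604,-0.6542447819618421,1.0717472684363727,1.479590953674277,0.5257890914166741,-0.19354788605838188,-0.8175263861623432,-0.26462613894432657,0.5289381801899268,0.44017239495814015,-1.3891708743678473,0
S0015,-0.6226889519567932,-1.3168019492698693,-1.148925219173421,-2.4554586671937892,-0.7440566149441615,-1.1464364519362864,-0.9059797615293215,-1.5349476291716408,-1.3564578804173448,0.22905682663334614,-1.5836404741499892,-1.9065507687304628,-0.1800361250818442,-0.13408587878221012,0.7524532932551751,0
S0016,-0.13542059806143902,0.3419337564002611,-0.07764798119355099,-0.4650450490302396,0.5127241687944035,0.9055364092582021,1.5093617674013018,0.07570105068235311,0.9713317640595692,0.03476127880793445,-0.4825140117690587,1.4594010094907084,0.4108730008076443,-0.02849761669334583,0.437221445275528,1
S0017,-0.7594132139469251,-1.2756257642211484,1.3273329250576094,-0.035576156151948646,-0.7023041579836747,1.5326997112921865,0.4684994254828613,0.16780868601486956,0.7212387015044217,0.0727611903089059,0.8299539026706507,-0.47482712891483925,0.6009076142563018,1.8520690474885217,0.7158175945517655,1
S0018,0.7931609880229955,-0.14663790567044627,2.256847201049762,0.5738687005578054,0.5474158334139028,-0.6766231535183838,0.6459435066490504,1.5758406888736143,0.4261599276688555,1.4399081585048972,1.3134175185068,-0.5822203230919445,1.066466643881952,-0.5556526300560323,-1.1203101417426344,0
S0019,-1.436969910878615,-1.9697870718218466,-2.1116282753317903,-0.9958087162411224,0.48914494677302817,-1.141569383992794,0.9334502138247214,-1.1392444206942671,-0.8702439229756587,-0.6661898520737938,-1.8098056036528687,-1.1349156175073973,-2.106050080817654,-1.8215162172833221,-0.6865417159296434,0
S0020,0.5827975692305636,1.3395070102389932,1.6264830054728343,0.13048284099450638,0.6508527040835819,1.0010353897104765,0.8970740600467144,1.0067150650126404,0.9692817190101548,-0.1868048460960462,0.3796243159324857,1.7923418050420052,0.3223368618980179,0.19756072812802758,0.9847642908007375,1
S0021,-0.8926334599210721,-1.0443828223350455,-0.5717357208957305,-0.3986545445384396,0.185363062248811,-0.5064481529720625,0.18863334350164312,-0.6960556514332128,-2.1758080319454822,0.08344188512385922,0.3114906467656047,0.35115772339299217,-0.92601561088545,0.03560129983687629,-0.015950497666775143,0
S0022,1.1947761771844019,0.05891525346494045,0.8039381667886152,0.9736604590699758,0.0669707843785903,-0.26607296557364346,-0.6771073795775696,-0.3666544164970561,0.4755671624831861,0.47474493220283764,-0.26961857121253696,0.4642482665304781,-0.8794678992480839,-0.6847555759441146,0.1606449015419041,1
S0023,0.014106617619649486,-0.15788228346603772,-2.2542871547584244,1.4245709540684104,0.1358862535651486,-0.08117669971117814,-0.10333663175889618,-0.9402491036633112,-0.26151140021480795,-1.2059577975539013,-1.3612762669746121,-2.3843651336312255,-1.3167099769175192,-1.531596292077982,-1.7907984048398056,1
S0024,0.2955318541860863,0.660399131427145,0.4224393605211604,-0.30047765745834765,-0.49236452687810306,0.10585071486560504,0.2850387837765218,1.3540254323217935,2.4905250961229037,0.5318544494149728,-0.2510351799098397,0.31555805563791,0.9788102533254164,0.054987787120540865,1.0957416548796663,1
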