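"node_id","x_mm","y_mm","z_mm","network_label"
"n001",-70,-100,-60,"SMN"
"n002",-53,-71,-37,"SMN"
"n003",-36,-42,-14,"SMN"
"n004",-19,-13,9,"SMN"
"n005",-2,16,32,"SMN"
"n006",15,45,55,"SMN"
"n007",32,-97,-53,"SMN"
"n008",49,-68,-30,"SMN"
"n009",66,-39,-7,"SMN"
"n010",-58,-10,16,"SMN"
"n011",-41,19,39,"SMN"
"n012",-24,48,62,"SMN"
"n013",-7,-94,-46,"SMN"
"n014",10,-65,-23,"SMN"
"n015",27,-36,0,"SMN"
"n016",44,-7,23,"SMN"
"n017",61,22,46,"SMN"
"n018",-63,51,69,"SMN"
"n019",-46,-91,-39,"SMN"
"n020",-29,-62,-16,"SMN"
"n021",-12,-33,7,"SMN"
"n022",5,-4,30,"SMN"
"n023",22,25,53,"VAN"
"n024",39,54,-55,"VAN"
"n025",56,-88,-32,"VAN"
"n026",-68,-59,-9,"VAN"
"n027",-51,-30,14,"VAN"
"n028",-34,-1,37,"VAN"
"n029",-17,28,60,"VAN"
"n030",0,57,-48,"VAN"
"n031",17,-85,-25,"VAN"
"n032",34,-56,-2,"VAN"
"n033",51,-27,21,"VAN"
"n034",68,2,44,"VAN"
"n035",-56,31,67,"VAN"
"n036",-39,60,-41,"VAN"
"n037",-22,-82,-18,"VAN"
"n038",-5,-53,5,"VAN"
"n039",12,-24,28,"VAN"
"n040",29,5,51,"VAN"
"n041",46,34,-57,"VAN"
"n042",63,63,-34,"VAN"
"n043",-61,-79,-11,"VAN"
"n044",-44,-50,12,"VAN"
"n045",-27,-21,35,"VN"
"n046",-10,8,58,"VN"
"n047",7,37,-50,"VN"
"n048",24,66,-27,"VN"
"n049",41,-76,-4,"VN"
"n050",58,-47,19,"VN"
"n051",-66,-18,42,"VN"
"n052",-49,11,65,"VN"
"n053",-32,40,-43,"VN"
"n054",-15,69,-20,"VN"
"n055",2,-73,3,"VN"
"n056",19,-44,26,"VN"
"n057",36,-15,49,"VN"
"n058",53,14,-59,"VN"
"n059",70,43,-36,"VN"
"n060",-54,-99,-13,"VN"
"n061",-37,-70,10,"VN"
"n062",-20,-41,33,"VN"
"n063",-3,-12,56,"VN"
"n064",14,17,-52,"VN"
"n065",31,46,-29,"VN"
"n066",48,-96,-6,"VN"
"n067",65,-67,17,"DAN"
"n068",-59,-38,40,"DAN"
"n069",-42,-9,63,"DAN"
"n070",-25,20,-45,"DAN"
"n071",-8,49,-22,"DAN"
"n072",9,-93,1,"DAN"
"n073",26,-64,24,"DAN"
"n074",43,-35,47,"DAN"
"n075",60,-6,70,"DAN"
"n076",-64,23,-38,"DAN"
"n077",-47,52,-15,"DAN"
"n078",-30,-90,8,"DAN"
"n079",-13,-61,31,"DAN"
"n080",4,-32,54,"DAN"
"n081",21,-3,-54,"DAN"
"n082",38,26,-31,"DAN"
"n083",55,55,-8,"DAN"
"n084",-69,-87,15,"DAN"
"n085",-52,-58,38,"DAN"
"n086",-35,-29,61,"DAN"
"n087",-18,0,-47,"DAN"
"n088",-1,29,-24,"DAN"
"n089",16,58,-1,"DMN"
"n090",33,-84,22,"DMN"
"n091",50,-55,45,"DMN"
"n092",67,-26,68,"DMN"
"n093",-57,3,-40,"DMN"
"n094",-40,32,-17,"DMN"
"n095",-23,61,6,"DMN"
"n096",-6,-81,29,"DMN"
"n097",11,-52,52,"DMN"
"n098",28,-23,-56,"DMN"
"n099",45,6,-33,"DMN"
"n100",62,35,-10,"DMN"
"n101",-62,64,13,"DMN"
"n102",-45,-78,36,"DMN"
"n103",-28,-49,59,"DMN"
"n104",-11,-20,-49,"DMN"
"n105",6,9,-26,"DMN"
"n106",23,38,-3,"DMN"
"n107",40,67,20,"DMN"
"n108",57,-75,43,"DMN"
"n109",-67,-46,66,"DMN"
"n110",-50,-17,-42,"DMN"
"n111",-33,12,-19,"FPN"
"n112",-16,41,4,"FPN"
"n113",1,70,27,"FPN"
"n114",18,-72,50,"FPN"
"n115",35,-43,-58,"FPN"
"n116",52,-14,-35,"FPN"
"n117",69,15,-12,"FPN"
"n118",-55,44,11,"FPN"
"n119",-38,-98,34,"FPN"
"n120",-21,-69,57,"FPN"
"n121",-4,-40,-51,"FPN"
"n122",13,-11,-28,"FPN"
"n123",30,18,-5,"FPN"
"n124",47,47,18,"FPN"
"n125",64,-95,41,"FPN"
"n126",-60,-66,64,"FPN"
"n127",-43,-37,-44,"FPN"
"n128",-26,-8,-21,"FPN"
"n129",-9,21,2,"FPN"
"n130",8,50,25,"FPN"
"n131",25,-92,48,"FPN"
"n132",42,-63,-60,"FPN"
"n133",59,-34,-37,"subcortical"
"n134",-65,-5,-14,"subcortical"
"n135",-48,24,9,"subcortical"
"n136",-31,53,32,"subcortical"
"n137",-14,-89,55,"subcortical"
"n138",3,-60,-53,"subcortical"
"n139",20,-31,-30,"subcortical"
"n140",37,-2,-7,"subcortical"
"n141",54,27,16,"subcortical"
"n142",-70,56,39,"subcortical"
"n143",-53,-86,62,"subcortical"
"n144",-36,-57,-46,"subcortical"
"n145",-19,-28,-23,"subcortical"
"n146",-2,1,0,"subcortical"
"n147",15,30,23,"subcortical"
"n148",32,59,46,"subcortical"
"n149",49,-83,69,"subcortical"
"n150",66,-54,-39,"subcortical"
"n151",-58,-25,-16,"subcortical"
"n152",-41,4,7,"subcortical"
"n153",-24,33,30,"subcortical"
"n154",-7,62,53,"subcortical"
"n155",10,-80,-55,"subcortical"
"n156",27,-51,-32,"subcortical"
"n157",44,-22,-9,"subcortical"
"n158",61,7,14,"subcortical"
"n159",-63,36,37,"subcortical"
"n160",-46,65,60,"subcortical"
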