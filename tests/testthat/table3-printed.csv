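type_name,scenario,le6,a7_12,a13_17,a18_59,ge60
Solanaceous Vegetables,A,0.01,0.00,0.00,0.00,0.00
Cruciferous Vegetables,A,0.01,0.00,0.00,0.01,0.00
Cucurbit Vegetables,A,0.01,0.00,0.00,0.00,0.00
Tuber and Root Vegetables,A,0.00,0.00,0.00,0.00,0.00
Aquatic Vegetables,A,0.01,0.01,0.01,0.01,0.01
Leafy Vegetables,A,0.01,0.00,0.00,0.00,0.00
Green Tea,A,0.00,0.00,0.00,0.00,0.00
Black Tea,A,0.00,0.00,0.00,0.00,0.00
Oolong Tea,A,0.00,0.00,0.00,0.00,0.00
Dark Tea,A,0.00,0.00,0.00,0.00,0.00
Fish,A,0.01,0.01,0.01,0.01,0.01
Crustaceans,A,0.01,0.01,0.01,0.00,0.00
Mollusks,A,0.01,0.01,0.01,0.01,0.01
Citrus Fruits,A,0.01,0.01,0.00,0.00,0.01
Melons and Gourd Fruits,A,0.01,0.01,0.01,0.01,0.01
Stone Fruits,A,0.01,0.01,0.01,0.00,0.00
Berries and Other Small Fruits,A,0.01,0.01,0.00,0.00,0.00
Tropical and Subtropical Fruits,A,0.01,0.01,0.00,0.00,0.00
Pome Fruits,A,0.01,0.01,0.01,0.01,0.01
Cereal-based Canned Foods,A,0.00,0.00,0.04,0.02,0.04
Canned Vegetables and Vegetable Products,A,0.00,0.07,0.00,0.04,0.03
Canned Fruits and Fruit Products,A,0.00,0.00,0.00,0.10,0.00
Canned Meat and Meat Products,A,0.01,0.01,0.01,0.01,0.01
Canned Aquatic Products,A,0.02,0.01,0.01,0.01,0.01
Canned Edible Fungi and Fungal Product,A,0.00,0.04,0.00,0.04,0.04
Solanaceous Vegetables,B,0.01,0.01,0.01,0.01,0.01
Cruciferous Vegetables,B,0.01,0.01,0.01,0.01,0.01
Cucurbit Vegetables,B,0.01,0.01,0.01,0.01,0.01
Tuber and Root Vegetables,B,0.01,0.01,0.01,0.01,0.01
Aquatic Vegetables,B,0.03,0.02,0.01,0.01,0.02
Leafy Vegetables,B,0.01,0.01,0.01,0.01,0.01
Green Tea,B,0.00,0.00,0.00,0.01,0.01
Black Tea,B,0.00,0.00,0.00,0.01,0.00
Oolong Tea,B,0.00,0.00,0.00,0.01,0.00
Dark Tea,B,0.00,0.00,0.00,0.00,0.00
Fish,B,0.03,0.02,0.01,0.02,0.02
Crustaceans,B,0.03,0.02,0.02,0.01,0.01
Mollusks,B,0.09,0.05,0.03,0.04,0.04
Citrus Fruits,B,0.02,0.01,0.01,0.01,0.01
Melons and Gourd Fruits,B,0.03,0.02,0.01,0.01,0.01
Stone Fruits,B,0.02,0.01,0.01,0.01,0.01
Berries and Other Small Fruits,B,0.02,0.01,0.01,0.01,0.01
Tropical and Subtropical Fruits,B,0.02,0.01,0.01,0.01,0.01
Pome Fruits,B,0.02,0.01,0.01,0.01,0.01
Cereal-based Canned Foods,B,0.00,0.00,0.04,0.04,0.06
Canned Vegetables and Vegetable Products,B,0.00,0.07,0.00,0.04,0.04
Canned Fruits and Fruit Products,B,0.00,0.00,0.00,0.10,0.00
Canned Meat and Meat Products,B,0.09,0.08,0.07,0.03,0.03
Canned Aquatic Products,B,0.10,0.09,0.08,0.03,0.03
Canned Edible Fungi and Fungal Product,B,0.00,0.05,0.00,0.05,0.04
Solanaceous Vegetables,C,0.68,0.48,0.42,0.42,0.45
Cruciferous Vegetables,C,0.08,0.07,0.06,0.10,0.05
Cucurbit Vegetables,C,0.09,0.07,0.06,0.06,0.06
Tuber and Root Vegetables,C,0.73,0.60,0.51,0.54,0.55
Aquatic Vegetables,C,0.07,0.06,0.06,0.05,0.05
Leafy Vegetables,C,0.52,0.49,0.39,0.33,0.34
Green Tea,C,0.00,0.01,0.02,0.02,0.02
Black Tea,C,0.00,0.03,0.02,0.01,0.01
Oolong Tea,C,0.00,0.00,0.00,0.01,0.03
Dark Tea,C,0.00,0.00,0.00,0.02,0.04
Fish,C,1.26,0.74,0.67,0.64,0.58
Crustaceans,C,0.26,0.15,0.12,0.10,0.09
Mollusks,C,0.08,0.05,0.04,0.03,0.03
Citrus Fruits,C,0.05,0.04,0.02,0.02,0.04
Melons and Gourd Fruits,C,0.09,0.06,0.05,0.04,0.05
Stone Fruits,C,0.05,0.04,0.03,0.02,0.02
Berries and Other Small Fruits,C,0.02,0.01,0.01,0.01,0.01
Tropical and Subtropical Fruits,C,0.03,0.02,0.01,0.01,0.01
Pome Fruits,C,0.18,0.13,0.09,0.08,0.08
Cereal-based Canned Foods,C,0.00,0.00,1.19,0.50,1.22
Canned Vegetables and Vegetable Products,C,0.00,3.04,0.00,1.65,1.27
Canned Fruits and Fruit Products,C,0.00,0.00,0.00,52.00,0.00
Canned Meat and Meat Products,C,1.72,1.35,1.31,1.10,0.75
Canned Aquatic Products,C,0.52,0.41,0.40,0.33,0.23
Canned Edible Fungi and Fungal Product,C,0.00,0.29,0.00,0.31,0.28
Solanaceous Vegetables,D,1.64,1.21,0.78,0.79,0.90
Cruciferous Vegetables,D,0.08,0.12,0.09,0.10,0.10
Cucurbit Vegetables,D,0.24,0.16,0.12,0.12,0.12
Tuber and Root Vegetables,D,1.68,1.49,0.95,1.08,1.11
Aquatic Vegetables,D,0.21,0.17,0.11,0.10,0.12
Leafy Vegetables,D,1.24,0.92,0.71,0.66,0.68
Green Tea,D,0.00,0.01,0.04,0.06,0.07
Black Tea,D,0.00,0.03,0.02,0.04,0.03
Oolong Tea,D,0.00,0.00,0.00,0.05,0.03
Dark Tea,D,0.00,0.00,0.00,0.01,0.02
Fish,D,2.51,2.23,1.43,1.61,1.66
Crustaceans,D,0.62,0.46,0.39,0.29,0.26
Mollusks,D,0.54,0.28,0.21,0.22,0.22
Citrus Fruits,D,0.11,0.07,0.05,0.04,0.04
Melons and Gourd Fruits,D,0.19,0.14,0.07,0.09,0.09
Stone Fruits,D,0.11,0.07,0.05,0.04,0.04
Berries and Other Small Fruits,D,0.04,0.03,0.02,0.02,0.02
Tropical and Subtropical Fruits,D,0.07,0.04,0.03,0.03,0.03
Pome Fruits,D,0.35,0.22,0.15,0.13,0.13
Cereal-based Canned Foods,D,0.00,0.00,1.19,1.21,1.60
Canned Vegetables and Vegetable Products,D,0.00,3.04,0.00,1.65,1.61
Canned Fruits and Fruit Products,D,0.00,0.00,0.00,52.00,0.00
Canned Meat and Meat Products,D,11.45,10.13,8.05,3.67,3.77
Canned Aquatic Products,D,2.92,2.58,2.22,0.93,0.96
Canned Edible Fungi and Fungal Product,D,0.00,0.42,0.00,0.36,0.28
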